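test_that("graphical interpolation follows the neighbor-displacement rule", {
  g <- build_embryo_graph()
  prev <- lattice_posture()
  ids <- seam_cell_ids()

  # no missing -> identity
  full <- interpolate_missing(prev$positions, prev, g)
  expect_equal(full$positions, prev$positions)
  expect_length(full$interpolated, 0L)

  # every neighbor of V3L moved by d -> V3L placed at previous + d
  d <- c(1.2, -0.7, 0.4)
  moved <- prev$positions + matrix(d, 20, 3, byrow = TRUE)
  moved["V3L", ] <- NA
  st <- interpolate_missing(moved, prev, g)
  expect_equal(unname(st$positions["V3L", ]),
               unname(prev$positions["V3L", ] + d))
  expect_identical(st$interpolated, "V3L")

  # random missing patterns against an independent ring-search oracle
  nbrs <- graph_neighbors(g)
  for (seed in 1:5) {
    set.seed(seed)
    miss <- sample(ids, sample(2:6, 1L))
    disp <- matrix(rnorm(60, sd = 1), 20, 3, dimnames = list(ids, NULL))
    pos <- prev$positions + disp
    pos[miss, ] <- NA
    st <- interpolate_missing(pos, prev, g)
    for (id in miss) {
      frontier <- id
      visited <- id
      repeat {
        frontier <- setdiff(unique(unlist(nbrs[frontier])), visited)
        visited <- c(visited, frontier)
        donors <- setdiff(frontier, miss)
        if (length(donors) || !length(frontier)) break
      }
      expected <- prev$positions[id, ] +
        colMeans(disp[donors, , drop = FALSE])
      expect_equal(unname(st$positions[id, ]), unname(expected))
    }
  }

  allNA <- prev$positions
  allNA[] <- NA
  expect_error(interpolate_missing(allNA, prev, g), "zero assigned")
})

test_that("self-intersection uses strict distance between non-adjacent midline segments", {
  expect_false(self_intersects(lattice_posture(), 2))

  # fold the midline back onto itself: posterior half overlaps anterior half
  ids <- seam_cell_ids()
  x <- c(0, 10, 20, 30, 40, 40, 30, 20, 10, 0)
  y <- c(0, 0, 0, 0, 0, 0.5, 0.5, 0.5, 0.5, 0.5)
  pos <- matrix(0, 20, 3, dimnames = list(ids, NULL))
  pos[, 1] <- rep(x, 2); pos[, 2] <- rep(y, 2)
  pos[, 3] <- rep(c(2, -2), each = 10)
  expect_true(self_intersects(posture_state(pos), 2))

  # two straight segments exactly min_separation apart are allowed
  y2 <- c(0, 0, 0, 0, 0, 2, 2, 2, 2, 2)
  pos[, 2] <- rep(y2, 2)
  expect_false(self_intersects(posture_state(pos), 2))
  expect_true(self_intersects(posture_state(pos), 2 + 1e-9))
})

test_that("noiseless detections are tracked without error or flags by every model", {
  sc <- flipping_scenario(31, n_frames = 10)
  g <- build_embryo_graph()
  det <- lapply(sc$truth_states, function(s) unname(s$positions))
  model <- benchmark_model()
  for (cm in c("gnn", "embryo", "posture", "movement", "pm")) {
    tr <- track_mhht(det, sc$seed_state, model = model, graph = g,
                     config = tracking_config(K = 2, N = 2, cost_model = cm,
                                              flag_threshold = 1e6))
    ev <- evaluate_posture_error(tr, sc$truth_states)
    expect_equal(ev$error_rate, 0)
    expect_false(any(tr$flagged))
  }
})

test_that("K = 1, N = 1 reduces MHHT to the gated GNN baseline exactly", {
  sc <- flipping_scenario(7, n_frames = 12)
  g <- build_embryo_graph()
  model <- benchmark_model()
  base <- track_mhht(sc$detections, sc$seed_state, graph = g,
                     config = tracking_config(K = 1, N = 1, cost_model = "gnn"))
  for (cm in c("embryo", "posture", "movement", "pm")) {
    red <- track_mhht(sc$detections, sc$seed_state, model = model, graph = g,
                      config = tracking_config(K = 1, N = 1, cost_model = cm))
    expect_identical(red$assignment, base$assignment)
  }
  # independent R reference: frame-by-frame optimal gated assignment
  cfg <- tracking_config(K = 1, N = 1, gate_radius_um = 6, cost_model = "gnn")
  cur <- sc$seed_state
  for (t in seq_along(sc$detections$detections)) {
    sol <- gated_k_best_assignments(cur, sc$detections$detections[[t]], cfg)[[1L]]
    expect_equal(unname(sol$assignment), unname(base$assignment[t, ]))
    pos <- cur$positions
    assigned <- !is.na(sol$assignment)
    pos[assigned, ] <- sc$detections$detections[[t]][sol$assignment[assigned], ]
    pos[!assigned, ] <- NA
    cur <- interpolate_missing(pos, cur, g)
  }
})

test_that("depth-2 lookahead resolves a clutter trap that defeats greedy GNN", {
  # nucleus A vanishes for one frame while clutter sits inside its gate;
  # B anchors the graph. GNN grabs the clutter; the deferred decision
  # prefers MISSING + reacquisition.
  seed <- posture_state(matrix(c(0, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE,
                               dimnames = list(c("A", "B"), NULL)))
  g <- build_embryo_graph(ids = c("A", "B"),
                          edges = data.frame(from = "A", to = "B"))
  det <- list(matrix(c(2.5, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE),
              matrix(c(0.3, 0, 0, 10, 0, 0), 2, 3, byrow = TRUE))
  gnn <- track_mhht(det, seed, graph = g,
                    config = tracking_config(K = 1, N = 1, gate_radius_um = 3,
                                             cost_model = "gnn",
                                             prune_self_intersections = FALSE))
  mhht <- track_mhht(det, seed, graph = g,
                     config = tracking_config(K = 2, N = 2, gate_radius_um = 3,
                                              cost_model = "gnn",
                                              prune_self_intersections = FALSE))
  expect_equal(unname(gnn$assignment[1L, "A"]), 1L)   # clutter committed
  expect_true(is.na(mhht$assignment[1L, "A"]))        # deferred: MISSING
  expect_equal(unname(mhht$assignment[2L, "A"]), 1L)  # reacquired
  expect_equal(unname(mhht$states[[1L]]$positions["A", ]), c(0, 0, 0))

  # exhaustive oracle over the full two-frame hypothesis tree
  gate <- 3
  cfg1 <- tracking_config(K = 10, N = 1, gate_radius_um = gate,
                          cost_model = "gnn")
  paths <- list()
  for (s1 in gated_k_best_assignments(seed, det[[1L]], cfg1)) {
    pos <- seed$positions
    a <- s1$assignment
    pos[!is.na(a), ] <- det[[1L]][a[!is.na(a)], ]
    pos[is.na(a), ] <- NA
    st1 <- if (all(is.na(a))) seed else interpolate_missing(pos, seed, g)
    for (s2 in gated_k_best_assignments(st1, det[[2L]], cfg1)) {
      paths[[length(paths) + 1L]] <-
        list(first = a, cost = s1$cost + s2$cost)
    }
  }
  best <- paths[[which.min(vapply(paths, `[[`, numeric(1L), "cost"))]]
  expect_identical(unname(best$first), unname(mhht$assignment[1L, ]))
})

test_that("flagging at the 99th percentile of clean costs covers erroneous frames", {
  g <- build_embryo_graph()
  model <- benchmark_model()
  # calibrate the threshold on true-assignment (noiseless) step costs
  cal <- flipping_scenario(55, n_frames = 30)
  det_clean <- lapply(cal$truth_states, function(s) unname(s$positions))
  clean <- track_mhht(det_clean, cal$seed_state, model = model, graph = g,
                      config = tracking_config(K = 1, N = 1, cost_model = "pm"))
  thr <- quantile(clean$step_cost, 0.99)

  hits <- 0L; errs <- 0L
  for (seed in 101:104) {
    sc <- flipping_scenario(seed, n_frames = 15)
    tr <- track_mhht(sc$detections, sc$seed_state, model = model, graph = g,
                     config = tracking_config(K = 2, N = 2, cost_model = "pm",
                                              flag_threshold = thr))
    ev <- evaluate_posture_error(tr, sc$truth_states,
                                 provenance = sc$detections$provenance,
                                 detections = sc$detections$detections)
    errs <- errs + sum(ev$frame_errors)
    hits <- hits + sum(ev$frame_errors & tr$flagged)
  }
  expect_gt(errs, 0L)           # the corruption produces real errors
  expect_equal(hits, errs)      # every erroneous frame is flagged
})

test_that("posture error evaluation counts forced scenarios exactly", {
  sc <- flipping_scenario(13, n_frames = 10)
  expect_equal(evaluate_posture_error(sc$truth_states, sc$truth_states)$error_rate, 0)

  # swap one lateral pair in exactly one of the frames
  states <- lapply(sc$truth_states, identity)
  p <- states[[4L]]$positions
  tmp <- p["V2L", ]; p["V2L", ] <- p["V2R", ]; p["V2R", ] <- tmp
  states[[4L]] <- posture_state(p, frame = states[[4L]]$frame)
  ev <- evaluate_posture_error(posture_sequence(states), sc$truth_states)
  expect_equal(ev$error_rate, 1 / length(states))
  expect_equal(sum(ev$confusion[c("V2L", "V2R")]), 2L)

  expect_error(evaluate_posture_error(posture_sequence(states[1:3]),
                                      sc$truth_states), "same number")
})

test_that("detection matching reports precision/recall/F1 per the forced arithmetic", {
  set.seed(9)
  ann <- matrix(runif(30, 0, 50), 10, 3)
  ident <- match_detections(ann, ann, max_dist_um = 2)
  expect_equal(c(ident$precision, ident$recall, ident$f1), c(1, 1, 1))

  with_clutter <- match_detections(rbind(ann, c(200, 200, 200)), ann,
                                   max_dist_um = 2)
  expect_equal(with_clutter$precision, 10 / 11)
  expect_equal(with_clutter$recall, 1)
  expect_equal(with_clutter$f1, 20 / 21)

  # jittered small sets against an exhaustive min-cost matching oracle
  for (trial in 1:10) {
    set.seed(trial)
    na <- sample(3:5, 1L)
    ann <- matrix(runif(na * 3, 0, 10), na, 3)
    det <- ann[sample(na), ] + matrix(rnorm(na * 3, sd = 0.3), na, 3)
    res <- match_detections(det, ann, max_dist_um = 2)
    d <- as.matrix(dist(rbind(det, ann)))[seq_len(na), na + seq_len(na)]
    feasible <- d <= 2
    perms <- function(v) {
      if (length(v) == 1L) return(list(v))
      out <- list()
      for (i in seq_along(v))
        for (p in perms(v[-i])) out <- c(out, list(c(v[i], p)))
      out
    }
    best <- Inf; best_n <- 0L
    for (p in perms(seq_len(na))) {
      ok <- feasible[cbind(seq_len(na), p)]
      nmatch <- sum(ok)
      cost <- sum(d[cbind(seq_len(na), p)][ok])
      if (nmatch > best_n || (nmatch == best_n && cost < best)) {
        best_n <- nmatch; best <- cost
      }
    }
    expect_equal(res$n_matched, best_n)
    expect_equal(sum(res$matches$distance), best, tolerance = 1e-9)
  }
})
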