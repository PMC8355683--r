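test_that("hourly discretization labels occupied hours by majority and gaps as absent", {
  ds <- tiny_ds(c("2007-05-01 09:10:00", "2007-05-01 09:50:00",
                  "2007-05-01 11:05:00"),
                c("R1", "R1", "R2"), rep("X", 3))
  seq_states <- discretize_hourly_states(ds, "X")
  expect_equal(as.vector(seq_states), c("R1", "ABSENT", "R2"))
  expect_equal(attr(seq_states, "start_hour"), utc("2007-05-01 09:00:00"))

  # everything in one hour -> single-state sequence
  ds2 <- tiny_ds(c("2007-05-01 09:01:00", "2007-05-01 09:59:00"),
                 c("R1", "R1"), rep("X", 2))
  expect_equal(as.vector(discretize_hourly_states(ds2, "X")), "R1")

  # within-hour majority, tie -> latest detection's node
  ds3 <- tiny_ds(paste0("2007-05-01 09:0", 1:4, ":00"),
                 c("R2", "R1", "R2", "R1"), rep("X", 4))
  expect_equal(as.vector(discretize_hourly_states(ds3, "X")), "R1")

  expect_equal(length(discretize_hourly_states(ds, "nobody")), 0)
})

test_that("lossless simulated sequences equal the generator's hourly ground truth", {
  sim <- small_sim(seed = 19, n_sharks = c(FB = 2), study_days = 15)
  ds <- merge_receiver_nodes(remove_false_detections(sim$detections))
  for (id in names(sim$truth$states)) {
    truth_lab <- sim$truth$state_labels[sim$truth$states[[id]]]
    got <- discretize_hourly_states(ds, id)
    # the empirical sequence spans first..last detection hour of the truth
    t0 <- sim$truth$start_hour[id]
    offset <- as.numeric(difftime(attr(got, "start_hour"), t0, units = "hours"))
    window <- truth_lab[(offset + 1):(offset + length(got))]
    expect_equal(as.vector(got), window)
    # no presence outside the detected window
    present <- truth_lab != "ABSENT"
    expect_true(all(which(present) > offset))
    expect_true(all(which(present) <= offset + length(got)))
  }
})

test_that("transition counting matches hand enumeration and is additive", {
  s <- c("A", "A", "ABSENT", "B", "B", "B", "ABSENT")
  m <- count_transitions(s)
  expect_equal(sum(m), length(s) - 1)
  expect_equal(m["A", "A"], 1L)
  expect_equal(m["A", "ABSENT"], 1L)
  expect_equal(m["ABSENT", "B"], 1L)
  expect_equal(m["B", "B"], 2L)
  expect_equal(m["B", "ABSENT"], 1L)
  expect_equal(m["ABSENT", "A"], 0L)

  # constant sequence: one diagonal cell holding n - 1
  cst <- count_transitions(rep("A", 7), states = c("A", "ABSENT"))
  expect_equal(cst["A", "A"], 6L)
  expect_equal(sum(cst), 6L)

  # additivity over independent sequences
  s1 <- c("A", "B", "A"); s2 <- c("B", "B", "ABSENT")
  states <- c("A", "B", "ABSENT")
  expect_equal(count_transitions(s1, states) + count_transitions(s2, states),
               count_transitions(s1, states) + count_transitions(s2, states))
  expect_equal(sum(count_transitions(s1, states) + count_transitions(s2, states)),
               (length(s1) - 1) + (length(s2) - 1))

  expect_warning(z <- count_transitions("A"), "shorter")
  expect_equal(sum(z), 0)
})

test_that("row normalization yields stochastic rows and drops unvisited states", {
  counts <- matrix(c(3L, 1L, 0L, 0L), 2, 2, byrow = TRUE,
                   dimnames = list(c("A", "B"), c("A", "B")))
  # B never left: dropped, A row renormalized over the remaining space
  P <- normalize_transitions(counts)
  expect_equal(attr(P, "dropped_states"), "B")
  expect_equal(dim(P), c(1, 1))
  expect_equal(unname(P[1, 1]), 1)

  counts2 <- matrix(c(3L, 1L, 2L, 4L), 2, 2, byrow = TRUE,
                    dimnames = list(c("A", "B"), c("A", "B")))
  P2 <- normalize_transitions(counts2)
  expect_equal(unname(P2["A", ]), c(0.75, 0.25))
  expect_equal(unname(rowSums(P2)), c(1, 1))

  # pooling then normalizing equals normalizing the summed matrix
  c1 <- count_transitions(c("A", "B", "A", "A"), c("A", "B"))
  c2 <- count_transitions(c("B", "A", "B", "B"), c("A", "B"))
  expect_equal(normalize_transitions(c1 + c2),
               normalize_transitions(c1 + c2))
  expect_error(normalize_transitions(matrix(0L, 2, 2,
                                            dimnames = list(c("A", "B"), c("A", "B")))),
               "all-zero")
})

test_that("power-method centrality equals the dense eigensolver's stationary distribution", {
  # 2-state chain solvable by hand: pi = (5/6, 1/6)
  P <- matrix(c(0.9, 0.1, 0.5, 0.5), 2, 2, byrow = TRUE,
              dimnames = list(c("a", "b"), c("a", "b")))
  pi_hat <- eigenvector_centrality_power(P)
  expect_equal(as.vector(pi_hat), c(5, 1) / 6, tolerance = 1e-9)
  expect_lt(max(abs(as.vector(pi_hat %*% P) - pi_hat)), 1e-8)

  # doubly stochastic -> uniform
  Q <- matrix(c(0.5, 0.3, 0.2,
                0.2, 0.5, 0.3,
                0.3, 0.2, 0.5), 3, 3, byrow = TRUE)
  dimnames(Q) <- list(letters[1:3], letters[1:3])
  expect_equal(as.vector(eigenvector_centrality_power(Q)), rep(1 / 3, 3),
               tolerance = 1e-9)

  # random chains up to 17 states vs eigen() on the transpose
  set.seed(99)
  for (n in c(5, 10, 17)) {
    M <- matrix(stats::rexp(n * n), n, n)
    M <- sweep(M, 1, rowSums(M), "/")
    dimnames(M) <- list(paste0("s", 1:n), paste0("s", 1:n))
    pi_pm <- eigenvector_centrality_power(M, tol = 1e-12)
    e <- eigen(t(M))
    v <- Re(e$vectors[, which.max(Re(e$values))])
    v <- v / sum(v)
    expect_equal(as.vector(pi_pm), v, tolerance = 1e-8)
  }

  expect_error(eigenvector_centrality_power(matrix(c(1, 1, 0, 1), 2, 2)),
               "row-stochastic")
})

test_that("periodic and reducible chains are handled by damping and restriction", {
  # period-2 chain whose stationary law is not uniform: plain iteration
  # oscillates from a uniform start, so lazy damping must kick in
  C <- matrix(c(0, 1, 0,
                0.5, 0, 0.5,
                0, 1, 0), 3, 3, byrow = TRUE,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  pi_c <- eigenvector_centrality_power(C)
  expect_equal(as.vector(pi_c), c(0.25, 0.5, 0.25), tolerance = 1e-6)
  expect_true(attr(pi_c, "damped"))

  # transient state feeding an absorbing pair: restricted to the closed class
  Pr <- matrix(c(0.0, 0.5, 0.5,
                 0.0, 0.6, 0.4,
                 0.0, 0.3, 0.7), 3, 3, byrow = TRUE,
               dimnames = list(c("t", "a", "b"), c("t", "a", "b")))
  pi_r <- eigenvector_centrality_power(Pr)
  expect_setequal(names(pi_r), c("a", "b"))
  expect_equal(sum(pi_r), 1)
})

test_that("node degree counts distinct connected neighbours, absent state excluded", {
  states <- c("A", "B", "C", "D", "ABSENT")
  cnt <- matrix(0L, 5, 5, dimnames = list(states, states))
  cnt["A", c("B", "C", "D")] <- 2L
  cnt["B", "A"] <- 1L
  cnt["A", "ABSENT"] <- 10L
  deg <- node_degree(cnt)
  expect_equal(deg[["A"]], 3L)
  expect_equal(deg[["B"]], 1L)
  expect_equal(deg[["D"]], 1L)   # incident edge counts regardless of direction
  diag_only <- diag(3L); dimnames(diag_only) <- list(c("A", "B", "C"), c("A", "B", "C"))
  expect_true(all(node_degree(diag_only) == 0))
})

test_that("a one-animal group chain equals that animal's individual chain", {
  sim <- small_sim(seed = 37, n_sharks = c(FA = 1, MC = 2), study_days = 20)
  ds <- merge_receiver_nodes(remove_false_detections(sim$detections))
  grp <- edmc(ds, group_by = "sex_size")
  ind <- edmc(ds, group_by = "individual")
  fa_id <- sim$truth$sharks$shark_id[sim$truth$sharks$sex == "F"]
  expect_equal(grp$chains[["FA"]]$counts, ind$chains[[fa_id]]$counts)
  expect_equal(grp$chains[["FA"]]$pi, ind$chains[[fa_id]]$pi)

  # pooled group counts are the sum of the members' counts
  mc_ids <- setdiff(sim$truth$sharks$shark_id, fa_id)
  expect_equal(grp$chains[["MC"]]$counts,
               Reduce("+", lapply(mc_ids, function(i) ind$chains[[i]]$counts)))

  # conservation: per-animal counts sum to sequence length - 1
  for (id in names(ind$chains)) {
    n_hours <- length(discretize_hourly_states(ds, id))
    expect_equal(ind$chains[[id]]$n_transitions, n_hours - 1)
  }
})

test_that("pooled empirical transition matrices recover the generating kernel within Monte-Carlo error", {
  sim <- small_sim(seed = 43, n_sharks = c(MC = 8), study_days = 120,
                   tagging_window_days = 0)
  ds <- merge_receiver_nodes(remove_false_detections(sim$detections))
  fit <- edmc(ds, group_by = "pooled")
  P_hat <- fit$chains[[1]]$P
  K <- sim$truth$kernels[["MC"]]
  counts <- fit$chains[[1]]$counts
  shared <- intersect(rownames(P_hat), rownames(K))
  for (s in shared) {
    n_row <- sum(counts[s, ])
    se <- sqrt(pmax(K[s, shared] * (1 - K[s, shared]), 1e-12) / max(n_row, 1))
    # 4 s.e. per cell: ~289 simultaneous comparisons across the matrix
    expect_true(all(abs(P_hat[s, shared] - K[s, shared]) <= 4 * se + 3 / n_row),
                label = paste("row", s, "within Monte-Carlo error of the kernel"))
  }
})

test_that("exported networks round-trip and validate", {
  sim <- small_sim(seed = 47, n_sharks = c(FC = 2), study_days = 20)
  ds <- merge_receiver_nodes(remove_false_detections(sim$detections))
  fit <- edmc(ds, group_by = "pooled")
  ch <- fit$chains[[1]]
  dir <- withr::local_tempdir()
  paths <- export_network(ch, dir)
  edges <- read_edge_list(paths[1])
  expect_equal(nrow(edges), sum(ch$counts > 0))
  back <- edges_to_counts(edges, states = rownames(ch$counts))
  expect_equal(back, ch$counts, ignore_attr = TRUE)
  expect_equal(rownames(back), rownames(ch$counts))

  # GraphML parses as XML and reloads with the same nodes and edge count
  doc <- xml2::read_xml(paths[2])
  expect_equal(xml2::xml_name(doc), "graphml")
  g <- igraph::read_graph(paths[2], format = "graphml")
  expect_equal(sort(igraph::V(g)$name), sort(rownames(ch$counts)))
  expect_equal(igraph::ecount(g), nrow(edges))
})
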