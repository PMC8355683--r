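ABSENT <- "ABSENT"

#' Hourly presence/absence state sequence
#'
#' Discretizes one animal's detections into clock-hour bins (UTC). Each hour
#' with at least one detection is labelled with the node holding the most
#' detections that hour (ties go to the node of the latest detection); hours
#' without detections are labelled `"ABSENT"`. The sequence spans the
#' animal's first through last detection hour — leading and trailing
#' unobservable periods are not padded, to avoid inflating the absent state.
#'
#' @param ds a cleaned, node-merged `"detection_set"`.
#' @param shark_id animal to extract.
#' @param pad_to_tag_life if `TRUE`, extend the sequence with `ABSENT` hours
#'   from tagging through nominal tag death (an alternative convention for
#'   studies that treat the tag as observable for its whole rated life).
#' @param cfg [study_config()], used only when padding.
#' @return Character vector of hourly state labels (possibly empty), with the
#'   first hour as attribute `"start_hour"`.
#' @export
discretize_hourly_states <- function(ds, shark_id, pad_to_tag_life = FALSE,
                                     cfg = study_config()) {
  stopifnot(inherits(ds, "detection_set"))
  ev <- ds$events[ds$events$transmitter_id == as.character(shark_id), , drop = FALSE]
  if (!nrow(ev)) return(character())
  node <- if (!is.null(ev$node_id)) ev$node_id else ev$receiver_id
  hour <- floor(as.numeric(ev$timestamp) / 3600)
  first <- min(hour); last <- max(hour)
  if (pad_to_tag_life) {
    sh <- ds$sharks[as.character(ds$sharks$shark_id) == as.character(shark_id), ]
    tagged <- as.POSIXct(paste(sh$date_tagged[1], "00:00:00"), tz = "UTC")
    first <- floor(as.numeric(tagged) / 3600)
    death <- min(as.Date(sh$date_tagged[1]) + cfg$tag_life_days, cfg$study_end)
    last <- floor(as.numeric(as.POSIXct(paste(death, "23:00:00"), tz = "UTC")) / 3600)
  }
  seq_states <- rep(ABSENT, last - first + 1)
  idx <- split(seq_along(hour), hour)
  for (hb in names(idx)) {
    i <- idx[[hb]]
    cnt <- table(node[i])
    best <- names(cnt)[cnt == max(cnt)]
    if (length(best) > 1) {
      late <- i[node[i] %in% best]
      best <- node[late[which.max(as.numeric(ev$timestamp[late]))]]
    }
    seq_states[as.numeric(hb) - first + 1] <- best
  }
  attr(seq_states, "start_hour") <- as.POSIXct(first * 3600,
                                               origin = "1970-01-01", tz = "UTC")
  seq_states
}

#' Transition count matrix of a state sequence
#'
#' Counts consecutive state pairs; the diagonal holds residency
#' self-transitions (and absent-state dwell). Counts sum to the sequence
#' length minus one, and counting two sequences separately then adding equals
#' counting their pooled transitions.
#'
#' @param seq_states character vector of state labels.
#' @param states state space (row/column order); defaults to the states seen,
#'   with `"ABSENT"` last.
#' @return Integer matrix `counts[s, s']`.
#' @export
count_transitions <- function(seq_states, states = NULL) {
  if (is.null(states)) {
    states <- sort(setdiff(unique(seq_states), ABSENT))
    if (ABSENT %in% seq_states || !length(states)) states <- c(states, ABSENT)
  }
  m <- matrix(0L, length(states), length(states),
              dimnames = list(from = states, to = states))
  n <- length(seq_states)
  if (n < 2) {
    warning("sequence shorter than 2: zero transition matrix")
    return(m)
  }
  from <- factor(seq_states[-n], levels = states)
  to <- factor(seq_states[-1], levels = states)
  tab <- table(from, to)
  m[] <- as.integer(tab)
  m
}

#' Row-normalize transition counts
#'
#' Converts counts to a row-stochastic transition matrix. States never left
#' (all-zero rows) carry no information about onward movement and are dropped
#' from the state space; the dropped labels are recorded in attribute
#' `"dropped_states"`. Dropping is iterated until the retained sub-matrix has
#' positive row sums.
#'
#' @param counts square count matrix (e.g. [count_transitions()], possibly
#'   pooled over animals by addition).
#' @return Row-stochastic matrix over the retained states.
#' @export
normalize_transitions <- function(counts) {
  if (!sum(counts) > 0) stop("all-zero transition count matrix")
  keep <- rownames(counts)
  dropped <- character()
  repeat {
    sub <- counts[keep, keep, drop = FALSE]
    rs <- rowSums(sub)
    if (all(rs > 0)) break
    dropped <- c(dropped, keep[rs == 0])
    keep <- keep[rs > 0]
    if (!length(keep)) stop("all-zero transition count matrix")
  }
  P <- sweep(counts[keep, keep, drop = FALSE], 1, rowSums(counts[keep, keep, drop = FALSE]), "/")
  attr(P, "dropped_states") <- dropped
  P
}

#' Stationary distribution by the power method
#'
#' Left dominant eigenvector of a row-stochastic transition matrix,
#' normalized to sum to one — the chain's stationary occupancy probabilities,
#' used as eigenvector centrality of the movement network. Power iteration
#' runs on the transpose (`pi <- pi P`); if the chain is reducible it is
#' first restricted to its largest strongly connected component (preferring
#' one containing the absent state), and if periodicity stalls convergence a
#' lazy-chain damping `P* = d P + (1-d) I` — which leaves the stationary
#' distribution unchanged — is applied.
#'
#' @param P row-stochastic matrix.
#' @param tol convergence tolerance on the successive-iterate infinity norm.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param damping lazy-chain mixing weight used only on stall.
#' @return Named numeric vector `pi` over the states of the restricted chain,
#'   `sum(pi) == 1`, with attributes `"iterations"`, `"restricted_to"` (states
#'   kept when reducible) and `"damped"` (logical).
#' @export
eigenvector_centrality_power <- function(P, tol = 1e-10, max_iter = 1e5,
                                         damping = 0.999) {
  stopifnot(is.matrix(P), nrow(P) == ncol(P))
  if (max(abs(rowSums(P) - 1)) > 1e-8) stop("P must be row-stochastic")
  states <- rownames(P)
  g <- igraph::graph_from_adjacency_matrix((P > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  restricted <- NULL
  if (comp$no > 1) {
    sizes <- comp$csize
    cand <- which(sizes == max(sizes))
    if (!is.null(states) && ABSENT %in% states) {
      a_comp <- comp$membership[match(ABSENT, states)]
      if (sizes[a_comp] == max(sizes)) cand <- a_comp
    }
    keep <- which(comp$membership == cand[1])
    restricted <- states[keep]
    P <- P[keep, keep, drop = FALSE]
    P <- sweep(P, 1, rowSums(P), "/")  # renormalize after restriction
  }
  run <- function(M, detect_stall = TRUE) {
    x <- rep(1 / nrow(M), nrow(M))
    x_prev <- x
    for (it in seq_len(max_iter)) {
      xn <- as.vector(x %*% M)
      xn <- xn / sum(xn)
      if (max(abs(xn - x)) < tol) return(list(pi = xn, it = it, ok = TRUE))
      # lag-2 convergence without lag-1 convergence: a period-2 oscillation
      if (detect_stall && it > 2 && max(abs(xn - x_prev)) < tol)
        return(list(pi = xn, it = it, ok = FALSE,
                    residual = max(abs(xn - x))))
      x_prev <- x
      x <- xn
    }
    list(pi = x, it = max_iter, ok = FALSE,
         residual = max(abs(as.vector(x %*% M) / sum(x %*% M) - x)))
  }
  res <- run(P)
  damped <- FALSE
  if (!res$ok) {  # periodic chain: damp with the identity (same fixed point)
    damped <- TRUE
    lazy <- damping * P + (1 - damping) * diag(nrow(P))
    res <- run(lazy, detect_stall = FALSE)  # lazy chains decay, not oscillate
    if (!res$ok)
      stop(sprintf("power iteration failed to converge in %d iterations (residual %.3g)",
                   max_iter, res$residual))
  }
  pi_hat <- stats::setNames(res$pi, rownames(P))
  attr(pi_hat, "iterations") <- res$it
  attr(pi_hat, "restricted_to") <- restricted
  attr(pi_hat, "damped") <- damped
  pi_hat
}

#' Node degree from transition counts
#'
#' Number of distinct *other* nodes with any incident (incoming or outgoing)
#' transition count, the node-size statistic of the movement network plots.
#'
#' @param counts square count matrix.
#' @param exclude_absent drop the absent state before computing degrees.
#' @return Named integer vector of degrees.
#' @export
node_degree <- function(counts, exclude_absent = TRUE) {
  if (exclude_absent && ABSENT %in% rownames(counts)) {
    keep <- setdiff(rownames(counts), ABSENT)
    counts <- counts[keep, keep, drop = FALSE]
  }
  adj <- (counts + t(counts)) > 0
  diag(adj) <- FALSE
  stats::setNames(as.integer(rowSums(adj)), rownames(counts))
}

.fit_chain <- function(seqs, states, label, sharks, tol, max_iter) {
  counts <- Reduce("+", lapply(seqs, count_transitions, states = states))
  P <- normalize_transitions(counts)
  pi_hat <- eigenvector_centrality_power(P, tol = tol, max_iter = max_iter)
  structure(list(label = label, sharks = sharks, states = rownames(P),
                 counts = counts, P = P, pi = pi_hat,
                 degree = node_degree(counts),
                 dropped_states = attr(P, "dropped_states"),
                 n_transitions = sum(counts)),
            class = "edmc_chain")
}

#' Empirically derived Markov chain movement networks
#'
#' Fits discrete-time Markov chains to hourly presence/absence sequences over
#' the array's nodes plus an absent state. For each group (by default sex by
#' size class) the member animals' transition counts are pooled, rows are
#' normalized to a transition matrix, and the stationary distribution — the
#' eigenvector centrality proxy for the probability of an animal being at a
#' given node — is computed by the power method.
#'
#' @param ds a cleaned, node-merged `"detection_set"` whose shark table has
#'   `sex` and `size_class`.
#' @param group_by `"sex_size"` (default; one chain per sex-by-size-class
#'   group), `"individual"` (one chain per animal) or `"pooled"` (one chain).
#' @param tol,max_iter power-method settings, see
#'   [eigenvector_centrality_power()].
#' @param pad_to_tag_life sequence convention, see
#'   [discretize_hourly_states()].
#' @return Object of class `"edmc"`: a list of `"edmc_chain"` results (one
#'   per group), each with the state space, pooled counts, transition matrix
#'   `P`, centrality `pi`, node degrees and dropped (unvisited) states.
#' @examples
#' \donttest{
#' sim <- simulate_cohort(simulation_config(
#'   seed = 1, n_sharks = c(FA = 2, FC = 2), study_days = 60))
#' ds <- merge_receiver_nodes(remove_false_detections(sim$detections))
#' fit <- edmc(ds)
#' summary(fit)
#' }
#' @export
edmc <- function(ds, group_by = c("sex_size", "individual", "pooled"),
                 tol = 1e-10, max_iter = 1e5, pad_to_tag_life = FALSE) {
  stopifnot(inherits(ds, "detection_set"))
  group_by <- match.arg(group_by)
  ids <- as.character(ds$sharks$shark_id)
  ids <- ids[ids %in% unique(ds$events$transmitter_id)]
  if (!length(ids)) stop("no detected animals in the detection set")
  map <- if (!is.null(ds$node_map)) ds$node_map else default_node_map(ds$stations$receiver_id)
  states <- c(sort(map$nodes), ABSENT)
  seqs <- lapply(ids, function(id)
    discretize_hourly_states(ds, id, pad_to_tag_life = pad_to_tag_life))
  names(seqs) <- ids
  seqs <- seqs[lengths(seqs) >= 2]
  if (!length(seqs)) stop("no animal has a state sequence of length >= 2")
  meta <- ds$sharks[match(names(seqs), as.character(ds$sharks$shark_id)), ]
  groups <- switch(group_by,
    sex_size = paste0(meta$sex, meta$size_class),
    individual = names(seqs),
    pooled = rep("all", length(seqs)))
  chains <- lapply(split(seq_along(seqs), groups), function(i)
    .fit_chain(seqs[i], states, label = unique(groups[i]),
               sharks = names(seqs)[i], tol = tol, max_iter = max_iter))
  structure(list(chains = chains, group_by = group_by, states = states,
                 n_sharks = length(seqs)),
            class = "edmc")
}

#' @export
print.edmc <- function(x, ...) {
  cat("Empirically derived Markov chain movement networks\n")
  cat("  grouping:", x$group_by, " (", length(x$chains), " chains, ",
      x$n_sharks, " animals)\n", sep = "")
  for (ch in x$chains)
    cat(sprintf("  %-6s %2d states, %6d transitions, pi(ABSENT) = %s\n",
                ch$label, length(ch$states), ch$n_transitions,
                if (ABSENT %in% names(ch$pi)) sprintf("%.3f", ch$pi[[ABSENT]]) else "-"))
  invisible(x)
}

#' @export
summary.edmc <- function(object, top = 3, ...) {
  cat("EDMC summary —", length(object$chains), "group chain(s)\n")
  for (ch in object$chains) {
    cat("\nGroup ", ch$label, " (", length(ch$sharks), " animals)\n", sep = "")
    pi_nodes <- ch$pi[setdiff(names(ch$pi), ABSENT)]
    ord <- order(pi_nodes, decreasing = TRUE)[seq_len(min(top, length(pi_nodes)))]
    if (ABSENT %in% names(ch$pi))
      cat(sprintf("  pi(ABSENT) = %.3f\n", ch$pi[[ABSENT]]))
    cat("  top nodes by centrality:",
        paste(sprintf("%s (%.3f)", names(pi_nodes)[ord], pi_nodes[ord]),
              collapse = ", "), "\n")
    if (length(ch$dropped_states))
      cat("  unvisited states dropped:", paste(ch$dropped_states, collapse = ", "), "\n")
  }
  invisible(object)
}

#' @export
coef.edmc <- function(object, ...) lapply(object$chains, `[[`, "P")

#' @export
plot.edmc <- function(x, group = 1, min_prob = 0, ...) {
  ch <- x$chains[[group]]
  keep <- setdiff(ch$states, ABSENT)
  P <- ch$P[intersect(keep, rownames(ch$P)), intersect(keep, colnames(ch$P)), drop = FALSE]
  P[P < min_prob] <- 0
  g <- igraph::graph_from_adjacency_matrix(P, mode = "directed", weighted = TRUE,
                                           diag = FALSE)
  deg <- ch$degree[igraph::V(g)$name]
  igraph::plot.igraph(g, vertex.size = 8 + 2 * deg,
                      edge.width = 1 + 4 * igraph::E(g)$weight,
                      edge.arrow.size = 0.4,
                      main = paste("Movement network:", ch$label), ...)
  invisible(x)
}

#' Simulate hourly state sequences from a fitted chain
#'
#' Draws Markov trajectories from a fitted group transition matrix, starting
#' from the stationary distribution — useful for posterior-predictive style
#' checks of dwell and absence run lengths.
#'
#' @param object an `"edmc"` fit.
#' @param nsim trajectory length in hours.
#' @param seed optional RNG seed.
#' @param group which group chain to simulate from.
#' @param ... unused.
#' @return Character vector of simulated state labels.
#' @export
simulate.edmc <- function(object, nsim = 1000, seed = NULL, group = 1, ...) {
  if (!is.null(seed)) set.seed(seed)
  ch <- object$chains[[group]]
  states <- rownames(ch$P)
  cum <- t(apply(ch$P, 1, cumsum))
  out <- character(nsim)
  s <- sample(length(states), 1, prob = pmax(ch$pi, 0))
  u <- stats::runif(nsim)
  for (i in seq_len(nsim)) {
    out[i] <- states[s]
    s <- findInterval(u[i], cum[s, ]) + 1L
  }
  out
}

#' Export a movement network
#'
#' Writes the edge list (`from`, `to`, `count`, `probability`) as CSV and the
#' full network as GraphML with centrality and degree node attributes.
#'
#' @param chain an `"edmc_chain"` (one element of an [edmc()] fit's
#'   `$chains`).
#' @param dir output directory.
#' @param prefix filename prefix (default the group label).
#' @return Invisibly, the two paths written.
#' @export
export_network <- function(chain, dir, prefix = chain$label) {
  stopifnot(inherits(chain, "edmc_chain"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  idx <- which(chain$counts > 0, arr.ind = TRUE)
  st <- rownames(chain$counts)
  edges <- data.frame(from = st[idx[, 1]], to = st[idx[, 2]],
                      count = chain$counts[idx],
                      probability = ifelse(st[idx[, 1]] %in% rownames(chain$P) &
                                             st[idx[, 2]] %in% colnames(chain$P),
                                           chain$P[cbind(match(st[idx[, 1]], rownames(chain$P)),
                                                         match(st[idx[, 2]], colnames(chain$P)))],
                                           NA_real_),
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  csv_path <- file.path(dir, paste0(prefix, "_edges.csv"))
  utils::write.csv(edges, csv_path, row.names = FALSE)
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = st,
                          centrality = as.numeric(chain$pi[st]),
                          degree = as.integer(node_degree(chain$counts,
                                                          exclude_absent = FALSE)[st])))
  gml_path <- file.path(dir, paste0(prefix, "_network.graphml"))
  igraph::write_graph(g, gml_path, format = "graphml")
  invisible(c(csv_path, gml_path))
}

#' @rdname export_network
#' @param path an edge-list CSV written by [export_network()].
#' @return `read_edge_list`: the edge data.frame, with the count matrix
#'   reconstructable via [edges_to_counts()].
#' @export
read_edge_list <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(from = "character", to = "character"))
}

#' @rdname export_network
#' @param edges an edge data.frame (`from`, `to`, `count`).
#' @param states optional state ordering.
#' @export
edges_to_counts <- function(edges, states = NULL) {
  if (is.null(states)) states <- sort(unique(c(edges$from, edges$to)))
  m <- matrix(0L, length(states), length(states),
              dimnames = list(from = states, to = states))
  m[cbind(match(edges$from, states), match(edges$to, states))] <- edges$count
  m
}
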