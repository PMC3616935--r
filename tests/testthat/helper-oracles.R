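# Shared fixtures and independent oracles used across the test files.

uniform_pi <- function(code = universal_code()) {
  rep(1 / length(code$sense_codons), length(code$sense_codons))
}

quartet_tree <- function() {
  read_tree(text = "((A:0.1,B:0.2):0.15,(C:0.12,D:0.3):0.08);")
}

# Exhaustive likelihood of one site on the quartet tree by summing over all
# internal-node state assignments (root r and the two cherry ancestors x, y):
#   L = sum_{r,x,y} pi_r P6(r,x) P7(r,y) PA(x,a) PB(x,b) PC(y,c) PD(y,d)
# written as an explicit enumeration via outer products, not tree pruning.
brute_quartet_loglik <- function(states, rm) {
  P <- lapply(c(A = 0.1, B = 0.2, C = 0.12, D = 0.3, n6 = 0.15, n7 = 0.08),
              function(t) transition_probs(rm, t))
  pi <- rm$pi
  a <- states["A"]; b <- states["B"]; cc <- states["C"]; d <- states["D"]
  Txy <- t(P$n6) %*% (pi * P$n7)              # T[x, y] = sum_r pi_r P6 P7
  down_x <- P$A[, a] * P$B[, b]
  down_y <- P$C[, cc] * P$D[, d]
  log(as.numeric(t(down_x) %*% Txy %*% down_y))
}

# All-pairs shortest-path centralities by exhaustive simple-path enumeration
# (independent of igraph).  adj: symmetric logical matrix.
brute_centralities <- function(adj) {
  n <- nrow(adj)
  all_paths <- function(from, to) {
    out <- list()
    walk <- function(path) {
      last <- path[length(path)]
      if (last == to) {
        out[[length(out) + 1]] <<- path
        return()
      }
      for (nxt in which(adj[last, ])) {
        if (!(nxt %in% path)) walk(c(path, nxt))
      }
    }
    walk(from)
    out
  }
  dist <- matrix(Inf, n, n)
  diag(dist) <- 0
  btw <- numeric(n)
  for (s in seq_len(n - 1)) {
    for (t in seq(s + 1, n)) {
      paths <- all_paths(s, t)
      if (length(paths) == 0) next
      lens <- vapply(paths, length, integer(1)) - 1L
      dmin <- min(lens)
      dist[s, t] <- dist[t, s] <- dmin
      shortest <- paths[lens == dmin]
      for (v in seq_len(n)) {
        if (v == s || v == t) next
        on_path <- vapply(shortest, function(p) v %in% p, logical(1))
        btw[v] <- btw[v] + mean(on_path)
      }
    }
  }
  comp <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (comp[v] == 0L) {
      cid <- cid + 1L
      comp[is.finite(dist[v, ])] <- cid
    }
  }
  clo <- vapply(seq_len(n), function(v) {
    same <- comp == comp[v]
    nc <- sum(same)
    if (nc < 2) return(NA_real_)
    (nc - 1) / sum(dist[v, same & seq_len(n) != v])
  }, numeric(1))
  list(degree = rowSums(adj), closeness = clo, betweenness = btw,
       component = comp)
}

random_adjacency <- function(n, p = 0.4) {
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      adj[i, j] <- adj[j, i] <- stats::runif(1) < p
    }
  }
  adj
}

adj_to_network <- function(adj) {
  nodes <- paste0("n", seq_len(nrow(adj)))
  idx <- which(adj & upper.tri(adj), arr.ind = TRUE)
  pathway_network(cbind(nodes[idx[, 1]], nodes[idx[, 2]]), nodes = nodes)
}

# quick fit configs used throughout the suite
fast_cfg <- function(...) fit_config(start_omega = 1, ...)
fixed_bl_cfg <- function(...) {
  fit_config(start_omega = 1, optimize_bl = FALSE, ...)
}
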