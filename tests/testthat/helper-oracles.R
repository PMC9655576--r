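# Brute-force graph oracles used to cross-check the igraph-backed
# metrics. Everything here is deliberately naive: Floyd-Warshall
# distances and exhaustive shortest-path enumeration on tiny graphs.

# adjacency matrix (directed, 0/1) -> hop-count distance matrix
fw_distances <- function(adj, directed = TRUE) {
  n <- nrow(adj)
  a <- adj > 0
  if (!directed) a <- a | t(a)
  d <- matrix(Inf, n, n)
  diag(d) <- 0
  d[a] <- 1
  for (k in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n)) {
    if (d[i, k] + d[k, j] < d[i, j]) d[i, j] <- d[i, k] + d[k, j]
  }
  d
}

oracle_efficiency <- function(adj, directed = FALSE) {
  d <- fw_distances(adj, directed)
  inv <- 1 / d
  diag(inv) <- 0
  sum(inv[is.finite(inv)]) / (nrow(adj) * (nrow(adj) - 1))
}

oracle_closeness <- function(adj, directed = FALSE) {
  d <- fw_distances(adj, directed)
  n <- nrow(adj)
  sapply(seq_len(n), function(i) {
    row <- d[i, -i]
    reach <- is.finite(row)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (n - 1)) * (r / sum(row[reach]))
  })
}

# count all shortest paths between every ordered pair by DFS enumeration
oracle_betweenness <- function(adj, directed = TRUE) {
  n <- nrow(adj)
  a <- adj > 0
  if (!directed) a <- a | t(a)
  d <- fw_distances(adj, directed)
  # paths_through[v]: sum over (s,t) of (# shortest s->t paths via v) / (# s->t paths)
  btw <- numeric(n)
  count_paths <- function(s, t) {
    # returns list(total = count, via = per-node counts of interior passages)
    via <- numeric(n)
    total <- 0
    walk <- function(v, len, interior) {
      if (v == t) {
        total <<- total + 1
        via[interior] <<- via[interior] + 1
        return(invisible())
      }
      if (len == d[s, t]) return(invisible())
      for (w in which(a[v, ])) {
        # only follow edges on some shortest path
        if (d[s, v] + 1 + d[w, t] == d[s, t] && d[s, w] == d[s, v] + 1) {
          walk(w, len + 1, if (w == t) interior else c(interior, w))
        }
      }
    }
    walk(s, 0, integer(0))
    list(total = total, via = via)
  }
  for (s in seq_len(n)) for (t in seq_len(n)) {
    if (s == t || !is.finite(d[s, t])) next
    cp <- count_paths(s, t)
    if (cp$total > 0) btw <- btw + cp$via / cp$total
  }
  denom <- if (directed) (n - 1) * (n - 2) else (n - 1) * (n - 2)
  # undirected graphs double-count each unordered pair, cancelling the
  # factor 2 in the usual normalisation
  btw / denom
}

# random small event logs / graphs for property tests
random_adj <- function(n, p = 0.35) {
  adj <- matrix(as.numeric(stats::runif(n * n) < p), n, n)
  diag(adj) <- 0
  adj
}

adj_to_events <- function(adj) {
  idx <- which(adj > 0, arr.ind = TRUE)
  if (nrow(idx) == 0) {
    return(tibble::tibble(donor = integer(), receiver = integer()))
  }
  tibble::tibble(donor = idx[, 1], receiver = idx[, 2])
}

# brute-force scan-sampling oracle: literally intersect every event with
# every scan instant, then merge runs by hand
oracle_scan <- function(events, scan_interval = 60, min_duration = 5,
                        horizon = NULL) {
  if (is.null(horizon)) horizon <- max(events$t_end, 0)
  scans <- seq(scan_interval, horizon + scan_interval, by = scan_interval)
  rows <- list()
  for (e in seq_len(nrow(events))) {
    ev <- events[e, ]
    if (ev$t_end - ev$t_start + 1 <= min_duration) next
    for (s in scans) {
      if (s >= ev$t_start && s <= ev$t_end) {
        rows[[length(rows) + 1]] <-
          data.frame(donor = ev$donor, receiver = ev$receiver, scan = s / scan_interval)
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble::tibble(donor = integer(), receiver = integer(),
                          first_scan_minute = integer(), duration_minutes = integer()))
  }
  df <- unique(do.call(rbind, rows))
  df <- df[order(df$donor, df$receiver, df$scan), ]
  out <- list()
  for (key in unique(paste(df$donor, df$receiver))) {
    sub <- df[paste(df$donor, df$receiver) == key, ]
    run_start <- sub$scan[1]
    len <- 1
    for (i in seq_len(nrow(sub))[-1]) {
      if (sub$scan[i] == sub$scan[i - 1] + 1) {
        len <- len + 1
      } else {
        out[[length(out) + 1]] <- data.frame(
          donor = sub$donor[1], receiver = sub$receiver[1],
          first_scan_minute = run_start, duration_minutes = len)
        run_start <- sub$scan[i]
        len <- 1
      }
    }
    out[[length(out) + 1]] <- data.frame(
      donor = sub$donor[1], receiver = sub$receiver[1],
      first_scan_minute = run_start, duration_minutes = len)
  }
  res <- tibble::as_tibble(do.call(rbind, out))
  res[order(res$first_scan_minute, res$donor, res$receiver), ]
}

# small, fast colony configuration for simulator tests
tiny_config <- function(n_ants = 12, n_steps = 400, alpha = NULL, ...) {
  if (is.null(alpha)) {
    alpha <- alpha_spec("power_law", exponent = 2, min_value = 1e-3,
                        max_value = 0.1, forager_multiplier = 2)
  }
  sim_config(n_ants = n_ants, n_steps = n_steps, alpha = alpha, ...)
}
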