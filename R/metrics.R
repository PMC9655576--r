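#' Build the weighted directed trophallactic network
#'
#' Nodes are all colony members (isolated, inactive ants included); a
#' directed edge donor -> receiver carries the number of events between
#' that ordered pair as its `weight` and the total amount of food moved
#' as `amount`.
#'
#' @param events Event tibble with `donor` and `receiver` columns (and
#'   optionally `amount`).
#' @param roster Either an integer vector of ant ids or a data frame with
#'   columns `id` and `caste`; every event participant must appear in it.
#' @return An [igraph][igraph::igraph-package] directed graph with vertex
#'   attributes `name` (id) and `caste` (if supplied).
#' @examples
#' ev <- tibble::tibble(donor = c(1, 1, 2), receiver = c(2, 2, 3))
#' net <- build_network(ev, roster = 1:4)
#' igraph::E(net)$weight
#' @export
build_network <- function(events, roster) {
  if (is.data.frame(roster)) {
    ids <- roster$id
    caste <- roster$caste
  } else {
    ids <- roster
    caste <- NULL
  }
  if (anyDuplicated(ids)) stop("duplicate ids in roster", call. = FALSE)
  if (nrow(events) > 0 &&
      !all(c(events$donor, events$receiver) %in% ids)) {
    stop("event participants missing from the roster", call. = FALSE)
  }
  if (nrow(events) > 0) {
    if (!"amount" %in% names(events)) events$amount <- NA_real_
    edges <- events |>
      dplyr::group_by(.data$donor, .data$receiver) |>
      dplyr::summarise(weight = dplyr::n(),
                       amount = sum(.data$amount), .groups = "drop")
  } else {
    edges <- tibble::tibble(donor = integer(), receiver = integer(),
                            weight = integer(), amount = double())
  }
  g <- igraph::graph_from_data_frame(
    edges, directed = TRUE,
    vertices = data.frame(name = as.character(ids))
  )
  if (!is.null(caste)) igraph::V(g)$caste <- as.character(caste)
  g
}

#' Global efficiency of the trophallactic network
#'
#' The mean, over all ordered pairs of distinct nodes, of the inverse
#' shortest-path distance `1/d(i, j)`, with `1/Inf = 0` for disconnected
#' pairs. Distances are unweighted hop counts; by default they are taken
#' on the undirected projection of the network. Efficiency ranges from 0
#' (no edges) to 1 (everyone directly connected) and proxies how fast
#' food can percolate through the colony.
#'
#' @param net An igraph network from [build_network()].
#' @param directed Use directed distances instead of the undirected
#'   projection (default `FALSE`).
#' @return A number in `[0, 1]`.
#' @export
global_efficiency <- function(net, directed = FALSE) {
  nv <- igraph::vcount(net)
  if (nv < 2) stop("efficiency needs at least 2 nodes", call. = FALSE)
  d <- igraph::distances(net, mode = if (directed) "out" else "all",
                         weights = NA)
  inv <- 1 / d
  diag(inv) <- 0
  inv[is.infinite(d)] <- 0
  sum(inv) / (nv * (nv - 1))
}

#' Per-node centralities of the trophallactic network
#'
#' Closeness, betweenness and clustering for every colony member, using
#' unweighted hop distances throughout:
#'
#' * closeness: `(r / (n - 1)) * (r / sum of distances to reachable
#'   nodes)` where `r` is the number of reachable nodes — the
#'   component-normalised form, 0 for isolates;
#' * betweenness: fraction of shortest paths between other node pairs
#'   passing through the node, on the directed graph by default,
#'   normalised to `[0, 1]`;
#' * clustering: local transitivity (share of closed triangles among the
#'   node's neighbour pairs) on the undirected projection, 0 for nodes of
#'   degree < 2.
#'
#' @param net An igraph network from [build_network()].
#' @param directed_betweenness Count directed shortest paths for
#'   betweenness (default `TRUE`).
#' @param directed_closeness Use directed (outward) distances for
#'   closeness (default `FALSE`).
#' @return A tibble with columns `id`, `closeness`, `betweenness`,
#'   `clustering`.
#' @export
node_centralities <- function(net, directed_betweenness = TRUE,
                              directed_closeness = FALSE) {
  nv <- igraph::vcount(net)
  if (nv < 2) stop("centralities need at least 2 nodes", call. = FALSE)
  d <- igraph::distances(net, mode = if (directed_closeness) "out" else "all",
                         weights = NA)
  diag(d) <- Inf
  closeness <- apply(d, 1, function(row) {
    reach <- is.finite(row)
    r <- sum(reach)
    if (r == 0) return(0)
    (r / (nv - 1)) * (r / sum(row[reach]))
  })
  btw <- igraph::betweenness(net, directed = directed_betweenness, weights = NA)
  denom <- if (directed_betweenness) (nv - 1) * (nv - 2) else (nv - 1) * (nv - 2) / 2
  btw <- if (denom > 0) btw / denom else rep(0, nv)
  clust <- igraph::transitivity(igraph::as_undirected(net, mode = "collapse"),
                                type = "local", isolates = "zero")
  tibble::tibble(
    id = igraph::V(net)$name,
    closeness = unname(closeness),
    betweenness = unname(btw),
    clustering = unname(clust)
  )
}

#' Lorenz curve and Gini coefficient of trophallactic activity
#'
#' Sorts the per-ant event counts in ascending order and accumulates
#' their shares. The Lorenz curve runs from (0, 0) to (1, 1); the Gini
#' coefficient is `1 - 2 * A` where `A` is the trapezoid area under the
#' curve, giving 0 for perfect equality and approaching 1 when a single
#' ant performs all events.
#'
#' @param counts Nonnegative per-ant activity counts, not all zero.
#' @return A list with `lorenz` (tibble of `p` = cumulative population
#'   share, `L` = cumulative activity share, including the (0,0) point)
#'   and `gini`.
#' @examples
#' lorenz_gini(c(0, 0, 0, 12))$gini  # 0.75
#' @export
lorenz_gini <- function(counts) {
  if (any(counts < 0) || anyNA(counts)) {
    stop("counts must be nonnegative", call. = FALSE)
  }
  total <- sum(counts)
  if (total == 0) stop("all-zero counts: Lorenz curve undefined", call. = FALSE)
  n <- length(counts)
  s <- sort(counts)
  L <- c(0, cumsum(s) / total)
  p <- c(0, seq_len(n) / n)
  area <- sum((L[-1] + L[-length(L)]) / 2 * diff(p))
  list(lorenz = tibble::tibble(p = p, L = L), gini = 1 - 2 * area)
}

#' Time by which half the trophallactic events have started
#'
#' @param events Event tibble with a `t_start` column (at least one row).
#' @return The smallest timestep `t` such that at least half of all
#'   events have `t_start <= t`.
#' @examples
#' t50(tibble::tibble(t_start = c(3, 7, 7, 900)))  # 7
#' @export
t50 <- function(events) {
  if (nrow(events) == 0) stop("empty event log: T50 undefined", call. = FALSE)
  ts <- sort(events$t_start)
  ts[ceiling(length(ts) / 2)]
}

#' Per-ant activity profile and distributions
#'
#' Counts, for every colony member, how many trophallactic events it gave
#' and received (inactive ants appear with zeros), split by caste.
#'
#' @param events Event tibble (`donor`, `receiver`).
#' @param roster Data frame with `id` and `caste`, or an id vector (all
#'   castes then `NA`).
#' @return A tibble with columns `id`, `caste`, `given`, `received`,
#'   `total`.
#' @seealso [activity_distributions()] for the histogram form.
#' @export
activity_profile <- function(events, roster) {
  if (!is.data.frame(roster)) {
    roster <- tibble::tibble(id = roster, caste = NA_character_)
  }
  if (nrow(events) > 0 &&
      !all(c(events$donor, events$receiver) %in% roster$id)) {
    stop("event participants missing from the roster", call. = FALSE)
  }
  given <- table(factor(events$donor, levels = roster$id))
  received <- table(factor(events$receiver, levels = roster$id))
  tibble::tibble(
    id = roster$id, caste = roster$caste,
    given = as.integer(given), received = as.integer(received),
    total = as.integer(given) + as.integer(received)
  )
}

#' Distributions of per-ant trophallactic activity
#'
#' The five distributions used to compare models with experiments: the
#' number of events per ant over the whole colony, and the given/received
#' events split by caste (forager vs non-forager). Zero-activity ants are
#' included.
#'
#' @inheritParams activity_profile
#' @return A tibble with columns `distribution` (one of `"all"`,
#'   `"F_given"`, `"F_received"`, `"NF_given"`, `"NF_received"`), `id`
#'   and `count`.
#' @export
activity_distributions <- function(events, roster) {
  prof <- activity_profile(events, roster)
  pick <- function(p, col) tibble::tibble(id = p$id, count = p[[col]])
  dplyr::bind_rows(
    dplyr::mutate(pick(prof, "total"), distribution = "all"),
    dplyr::mutate(pick(dplyr::filter(prof, .data$caste == "F"), "given"),
                  distribution = "F_given"),
    dplyr::mutate(pick(dplyr::filter(prof, .data$caste == "F"), "received"),
                  distribution = "F_received"),
    dplyr::mutate(pick(dplyr::filter(prof, .data$caste == "NF"), "given"),
                  distribution = "NF_given"),
    dplyr::mutate(pick(dplyr::filter(prof, .data$caste == "NF"), "received"),
                  distribution = "NF_received")
  ) |>
    dplyr::select("distribution", "id", "count")
}

#' Export a network as an edge-list table
#'
#' @param net An igraph network from [build_network()].
#' @return A tibble `donor`, `receiver`, `weight`, `amount`.
#' @export
network_edge_list <- function(net) {
  if (igraph::ecount(net) == 0) {
    return(tibble::tibble(donor = character(), receiver = character(),
                          weight = numeric(), amount = numeric()))
  }
  el <- igraph::as_data_frame(net, what = "edges")
  tibble::as_tibble(el) |>
    dplyr::rename(donor = "from", receiver = "to")
}
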