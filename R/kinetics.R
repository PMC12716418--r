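#' Kinetic master-equation model with a core trap
#'
#' Assembles the rate matrix `K` of the master equation `dp/dt = K p` from
#' the full (uncut) cluster rate table: `K[j, i] = k_{i->j}` for `i != j`,
#' diagonals the negated column outflow sums. An explicit absorbing state
#' `"trap"` receives irreversible flux from the trap cluster (photochemical
#' quenching in the core) at `trap_rate_per_ps`, so every column of `K`
#' sums to zero and total probability (transient + absorbed) is conserved.
#'
#' @param table a cluster rate table (tibble with `donor`, `acceptor`,
#'   `rate_per_ps`).
#' @param trap_state name of the state feeding the trap (default
#'   `"core"`).
#' @param trap_rate_per_ps irreversible trapping rate out of that state.
#' @return an object of class `eet_kinetic_model` with `states`, `K`, and
#'   the trap specification.
#' @export
build_kinetic_model <- function(table, trap_state = "core",
                                trap_rate_per_ps = 1) {
  if (!nrow(table)) abort("empty rate table")
  states <- sort(unique(c(table$donor, table$acceptor)))
  if (!(trap_state %in% states)) {
    abort(paste0("trap state '", trap_state, "' not present in the table"))
  }
  n <- length(states)
  K <- matrix(0, n + 1, n + 1,
              dimnames = list(c(states, "trap"), c(states, "trap")))
  for (r in seq_len(nrow(table))) {
    i <- match(table$donor[r], states)
    j <- match(table$acceptor[r], states)
    k <- table$rate_per_ps[r]
    if (!is.finite(k) || k < 0) abort("rates must be finite and >= 0")
    K[j, i] <- K[j, i] + k
  }
  K["trap", trap_state] <- K["trap", trap_state] + trap_rate_per_ps
  diag(K) <- diag(K) - colSums(K)
  structure(list(states = c(states, "trap"), K = K,
                 trap_state = trap_state,
                 trap_rate_per_ps = trap_rate_per_ps),
            class = "eet_kinetic_model")
}

#' Solve the kinetic master equation
#'
#' Eigen-decomposition of the rate matrix gives
#' `p(t) = sum_k a_k v_k exp(lambda_k t)`; decaying modes are reported as
#' lifetimes `tau_k = -1/lambda_k`. If the eigenvector matrix is close to
#' defective the solver falls back to numerical propagation with a warning
#' (then only `occupancy()` is available).
#'
#' @param model an `eet_kinetic_model`.
#' @param p0 initial occupancy, either a named vector over states or a
#'   single state name; normalized to sum 1.
#' @return an object of class `eet_kinetic_solution` with `lifetimes_ps`
#'   (decaying modes, ascending), `amplitudes` (per state and mode), and
#'   `occupancy(times)` returning a tibble of occupancies.
#' @export
solve_kinetics <- function(model, p0) {
  stopifnot(inherits(model, "eet_kinetic_model"))
  states <- model$states
  if (is.character(p0) && length(p0) == 1) {
    v <- setNames(numeric(length(states)), states)
    if (!(p0 %in% states)) abort(paste0("unknown initial state: ", p0))
    v[p0] <- 1
    p0 <- v
  }
  p0 <- p0[states]
  if (any(is.na(p0)) || any(p0 < 0)) abort("invalid initial occupancy")
  p0 <- p0 / sum(p0)
  K <- model$K
  eig <- eigen(K)
  rc <- rcond(eig$vectors)
  if (rc < 1e-10) {
    warn("near-defective rate matrix; falling back to numerical propagation")
    occupancy <- function(times) .propagate_expm(K, p0, times, states)
    return(structure(list(lifetimes_ps = NULL, amplitudes = NULL,
                          occupancy = occupancy, states = states,
                          defective = TRUE),
                     class = "eet_kinetic_solution"))
  }
  a <- solve(eig$vectors, p0)
  lam <- eig$values
  decaying <- Re(lam) < -1e-12
  lifetimes <- sort(-1 / Re(lam[decaying]))
  modes <- sweep(eig$vectors, 2, a, `*`) # state x mode contributions
  occupancy <- function(times) {
    pt <- Re(modes %*% exp(outer(lam, times)))
    tibble(time_ps = rep(times, each = length(states)),
           state = rep(states, length(times)),
           occupancy = as.vector(pt))
  }
  structure(list(lifetimes_ps = lifetimes,
                 amplitudes = Re(modes),
                 eigenvalues = lam,
                 occupancy = occupancy, states = states,
                 defective = FALSE),
            class = "eet_kinetic_solution")
}

# dense scaling-and-squaring propagation fallback (small state spaces)
.propagate_expm <- function(K, p0, times, states) {
  res <- lapply(times, function(t) {
    # 4th-order Taylor with scaling and squaring
    m <- max(0, ceiling(log2(max(1e-12, max(abs(K)) * abs(t)))) + 4)
    A <- K * (t / 2^m)
    E <- diag(nrow(K)) + A + A %*% A / 2 + A %*% A %*% A / 6 +
      A %*% A %*% A %*% A / 24
    for (i in seq_len(m)) E <- E %*% E
    as.vector(E %*% p0)
  })
  tibble(time_ps = rep(times, each = length(states)),
         state = rep(states, length(times)),
         occupancy = unlist(res))
}

#' @export
tidy.eet_kinetic_solution <- function(x, ...) {
  if (is.null(x$lifetimes_ps)) return(tibble())
  tibble(mode = seq_along(x$lifetimes_ps), lifetime_ps = x$lifetimes_ps)
}

#' @export
print.eet_kinetic_solution <- function(x, ...) {
  cat("<eet_kinetic_solution> ", length(x$states), " states\n", sep = "")
  if (!is.null(x$lifetimes_ps)) {
    cat("  eigen-lifetimes (ps): ",
        paste(signif(head(x$lifetimes_ps, 6), 4), collapse = ", "),
        if (length(x$lifetimes_ps) > 6) ", ...", "\n", sep = "")
  }
  invisible(x)
}

#' Mean first-passage time to the trap
#'
#' Solves the linear system over transient states: with `A` the transient
#' block of `K`, the MFPT vector satisfies `t(A) tau = -1`. Sources from
#' which the trap is unreachable get `Inf`.
#'
#' @param model an `eet_kinetic_model`.
#' @param source state name (or vector of names) to report.
#' @return named numeric vector of MFPTs (ps).
#' @export
mfpt_to_trap <- function(model, source = NULL) {
  stopifnot(inherits(model, "eet_kinetic_model"))
  states <- model$states
  trans <- setdiff(states, "trap")
  A <- model$K[trans, trans, drop = FALSE]
  tau <- setNames(rep(Inf, length(trans)), trans)
  ok <- .reaches_trap(model)
  if (any(ok)) {
    sub <- A[ok, ok, drop = FALSE]
    tau[ok] <- solve(t(sub), rep(-1, sum(ok)))
  }
  if (is.null(source)) tau else {
    if (!all(source %in% trans)) abort("unknown source state")
    tau[source]
  }
}

# which transient states can reach the trap (graph reachability on the
# directed rate graph)
.reaches_trap <- function(model) {
  K <- model$K
  states <- model$states
  trans <- setdiff(states, "trap")
  adj <- K > 0
  diag(adj) <- FALSE
  reach <- setNames(states == "trap", states)
  repeat {
    new <- reach | apply(adj & matrix(reach, nrow(K), ncol(K),
                                      byrow = FALSE), 2, any)
    # state i reaches trap if any j with K[j,i]>0 reaches trap
    if (all(new == reach)) break
    reach <- new
  }
  reach[trans]
}

#' Fastest antenna-to-core route
#'
#' Finds the directed path from `source` to `sink` minimizing the sum of
#' stepwise time constants, using only edges with `tau <= cutoff_ps` (the
#' map-rendering rule). Ties are broken deterministically by lexicographic
#' comparison of the subunit name sequence. The route time constant is the
#' sum of the step time constants.
#'
#' @param table a cluster rate table (tibble with `donor`, `acceptor`,
#'   `tau_ps`).
#' @param source,sink state names.
#' @param cutoff_ps slowest admissible step (default 25 ps).
#' @return a list of class `eet_route`: `path` (state sequence),
#'   `step_tau_ps`, `route_tau_ps` (`Inf` and empty path when no
#'   admissible route exists).
#' @export
best_route <- function(table, source, sink, cutoff_ps = 25) {
  edges <- table[is.finite(table$tau_ps) & table$tau_ps <= cutoff_ps, ,
                 drop = FALSE]
  no_route <- structure(list(source = source, sink = sink,
                             path = character(), step_tau_ps = numeric(),
                             route_tau_ps = Inf),
                        class = "eet_route")
  if (!nrow(edges) || !(source %in% edges$donor)) return(no_route)
  verts <- sort(unique(c(edges$donor, edges$acceptor, source, sink)))
  g <- igraph::graph_from_data_frame(
    data.frame(from = edges$donor, to = edges$acceptor,
               weight = edges$tau_ps),
    directed = TRUE,
    vertices = data.frame(name = verts))
  suppressWarnings({
    asp <- igraph::all_shortest_paths(g, from = source, to = sink,
                                      mode = "out", weights = NULL)
  })
  if (!length(asp$res)) return(no_route)
  paths <- lapply(asp$res, function(p) names(igraph::as_ids(p)) %||%
                    igraph::as_ids(p))
  # deterministic lexicographic tie-break on the name sequence
  keys <- map_chr(paths, paste, collapse = "")
  path <- paths[[order(keys)[1]]]
  step <- map_dbl(seq_len(length(path) - 1), function(i) {
    cand <- edges$tau_ps[edges$donor == path[i] &
                           edges$acceptor == path[i + 1]]
    min(cand)
  })
  structure(list(source = source, sink = sink, path = path,
                 step_tau_ps = step, route_tau_ps = sum(step)),
            class = "eet_route")
}

#' @export
print.eet_route <- function(x, ...) {
  if (!length(x$path)) {
    cat("<eet_route> ", x$source, " -> ", x$sink, ": no admissible route\n",
        sep = "")
  } else {
    cat("<eet_route> ", paste(x$path, collapse = " -> "), " (",
        signif(x$route_tau_ps, 4), " ps)\n", sep = "")
  }
  invisible(x)
}

#' Layer-averaged antenna-to-core route time constant
#'
#' For every antenna subunit in the given layers, finds the best route to
#' the core ([best_route()]) and the mean first-passage time of the full
#' kinetic model, and averages both over the routable sources. Sources
#' without an admissible route are listed with a warning and excluded from
#' the mean.
#'
#' @param table a cluster rate table ([cluster_network()]).
#' @param layers integer layers to pool (e.g. `c(5, 6)`).
#' @param sink core state name.
#' @param cutoff_ps routing cutoff (25 ps).
#' @param trap_rate_per_ps trapping rate used for the MFPT co-report.
#' @return an object of class `eet_route_summary`: `per_source` tibble
#'   (`source`, `layer`, `route_tau_ps`, `mfpt_ps`, `path`),
#'   `mean_route_tau_ps`, `mean_mfpt_ps`.
#' @export
layer_average_route_time <- function(table, layers, sink = "core",
                                     cutoff_ps = 25,
                                     trap_rate_per_ps = 1) {
  stopifnot(all(c("donor_layer", "donor") %in% names(table)))
  sources <- sort(unique(table$donor[table$donor_layer %in% layers]))
  if (!length(sources)) abort("no subunits in the requested layers")
  routes <- map(sources, best_route, table = table, sink = sink,
                cutoff_ps = cutoff_ps)
  km <- build_kinetic_model(table[table$rate_per_ps > 0, , drop = FALSE],
                            trap_state = sink,
                            trap_rate_per_ps = trap_rate_per_ps)
  mfpt <- mfpt_to_trap(km)[sources]
  per <- tibble(
    source = sources,
    layer = map_dbl(sources, function(s) {
      table$donor_layer[match(s, table$donor)]
    }),
    route_tau_ps = map_dbl(routes, "route_tau_ps"),
    mfpt_ps = unname(mfpt),
    path = map_chr(routes, function(r) paste(r$path, collapse = " -> "))
  )
  unroutable <- per$source[!is.finite(per$route_tau_ps)]
  if (length(unroutable)) {
    warn(paste0("sources without an admissible route (excluded from the ",
                "mean): ", paste(unroutable, collapse = ", ")))
  }
  ok <- is.finite(per$route_tau_ps)
  structure(list(per_source = per,
                 mean_route_tau_ps = mean(per$route_tau_ps[ok]),
                 mean_mfpt_ps = mean(per$mfpt_ps[is.finite(per$mfpt_ps)])),
            class = "eet_route_summary")
}

#' @export
print.eet_route_summary <- function(x, ...) {
  cat("<eet_route_summary> ", nrow(x$per_source), " sources; mean route ",
      signif(x$mean_route_tau_ps, 4), " ps; mean MFPT ",
      signif(x$mean_mfpt_ps, 4), " ps\n", sep = "")
  invisible(x)
}

#' @export
tidy.eet_route_summary <- function(x, ...) x$per_source

#' @export
glance.eet_route_summary <- function(x, ...) {
  tibble(n_sources = nrow(x$per_source),
         mean_route_tau_ps = x$mean_route_tau_ps,
         mean_mfpt_ps = x$mean_mfpt_ps)
}

#' Write routes as JSON and DOT
#'
#' @param summary an `eet_route_summary`.
#' @param json,dot output paths (either may be `NULL`).
#' @return `summary`, invisibly.
#' @export
write_routes <- function(summary, json = NULL, dot = NULL) {
  stopifnot(inherits(summary, "eet_route_summary"))
  if (!is.null(json)) {
    jsonlite::write_json(
      list(per_source = as.data.frame(summary$per_source),
           mean_route_tau_ps = summary$mean_route_tau_ps,
           mean_mfpt_ps = summary$mean_mfpt_ps),
      json, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(dot)) {
    edges <- unique(unlist(map(summary$per_source$path, function(p) {
      st <- strsplit(p, " -> ", fixed = TRUE)[[1]]
      if (length(st) < 2) character() else
        paste0('  "', head(st, -1), '" -> "', tail(st, -1), '";')
    })))
    writeLines(c("digraph routes {", edges, "}"), dot)
  }
  invisible(summary)
}
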