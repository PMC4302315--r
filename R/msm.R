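#' Count transitions between states at a lag time
#'
#' Builds the transition count matrix `C[i, j]`: the number of observed
#' transitions from state `i` at time `t` to state `j` at time `t + lag`.
#' Trajectories are counted independently (no pair spans a trajectory
#' boundary). Sliding-window counting uses every frame `t` with `t + lag`
#' inside the same trajectory; independent-sample counting subsamples each
#' trajectory at the lag before counting consecutive pairs.
#'
#' @param dtrajs list of integer state sequences (one per trajectory), or an
#'   assignment data frame from [assign_frames()].
#' @param lag lag time in ns; must be a positive integer multiple of
#'   `spacing`.
#' @param spacing frame spacing in ns.
#' @param sliding logical; sliding-window counting (default `TRUE`).
#' @param n_states state-space size `K`; default the maximum observed index.
#' @return an object of class `CountMatrix`: list with integer matrix `C`
#'   (`K x K`), `lag` (ns), `lag_frames`, `sliding`, `K`.
#' @export
count_transitions <- function(dtrajs, lag, spacing = 1, sliding = TRUE,
                              n_states = NULL) {
  if (is.data.frame(dtrajs)) dtrajs <- assignment_sequences(dtrajs)
  lag_frames <- lag / spacing
  if (lag_frames < 1 - 1e-9 || abs(lag_frames - round(lag_frames)) > 1e-9)
    stop(sprintf("lag (%g ns) must be a positive integer multiple of the frame spacing (%g ns)",
                 lag, spacing))
  lag_frames <- as.integer(round(lag_frames))
  K <- n_states %||% max(unlist(dtrajs))
  C <- matrix(0L, K, K)
  for (s in dtrajs) {
    len <- length(s)
    if (len <= lag_frames) next
    if (sliding) {
      from <- s[seq_len(len - lag_frames)]
      to <- s[seq_len(len - lag_frames) + lag_frames]
    } else {
      sub <- s[seq(1L, len, by = lag_frames)]
      from <- sub[-length(sub)]
      to <- sub[-1L]
    }
    tab <- table(factor(from, levels = seq_len(K)),
                 factor(to, levels = seq_len(K)))
    C <- C + matrix(as.integer(tab), K, K)
  }
  structure(list(C = C, lag = lag, lag_frames = lag_frames,
                 sliding = sliding, K = K),
            class = "CountMatrix")
}

#' Restrict counts to the largest ergodic (strongly connected) set
#'
#' A stationary distribution is only defined on a communicating state set.
#' This restricts the count matrix to the largest strongly connected
#' component of the directed graph with an edge `i -> j` wherever
#' `C[i, j] > 0`, and records the mapping back to the original state
#' indices.
#'
#' @param counts a `CountMatrix`.
#' @return a `CountMatrix` with extra fields `mapping` (retained original
#'   state indices, 1-based) and `dropped` (removed original indices).
#' @export
ergodic_trim <- function(counts) {
  C <- counts$C
  if (all(C == 0)) stop("all transition counts are zero; no ergodic component")
  g <- igraph::graph_from_adjacency_matrix((C > 0) * 1, mode = "directed")
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  # tie-break: component containing the lowest original state index
  if (length(best) > 1L)
    best <- best[which.min(vapply(best, function(b) min(which(comp$membership == b)),
                                  numeric(1)))]
  keep <- which(comp$membership == best)
  if (length(keep) == 1L)
    warning("ergodic trim left a single state; the model is degenerate")
  out <- counts
  out$C <- C[keep, keep, drop = FALSE]
  out$K <- length(keep)
  out$mapping <- keep
  out$dropped <- setdiff(seq_len(ncol(C)), keep)
  out
}

#' Estimate a transition matrix and equilibrium populations
#'
#' Maximum-likelihood estimation of the row-stochastic transition matrix
#' `P` at the count matrix's lag time. `"naive"` mode is plain row
#' normalization `P[i, j] = C[i, j] / sum_j C[i, j]` with the stationary
#' distribution taken as the leading left eigenvector. `"reversible-mle"`
#' maximizes the multinomial likelihood subject to detailed balance
#' (`pi_i P_ij = pi_j P_ji`) by the standard self-consistent fixed-point
#' iteration on symmetrized auxiliary counts `x_ij`, iterated until the
#' largest element change of the normalized `x` falls below `tol` (default
#' 1e-10) or `max_iter` sweeps; the stationary distribution comes directly
#' from the reversible parametrization.
#'
#' @param counts a `CountMatrix`, ergodically trimmed ([ergodic_trim()]).
#' @param mode `"reversible-mle"` (default) or `"naive"`.
#' @param tol convergence tolerance for the reversible fixed point.
#' @param max_iter maximum number of fixed-point sweeps.
#' @return an object of class `TransitionModel`: list with `P`, `pi`,
#'   `eigenvalues` (sorted by decreasing modulus), `lag` (ns), `mode`, `K`,
#'   and `mapping` to original cluster indices.
#' @export
estimate_transition_matrix <- function(counts, mode = c("reversible-mle", "naive"),
                                       tol = 1e-10, max_iter = 10000L) {
  mode <- match.arg(mode)
  C <- counts$C
  rs <- rowSums(C)
  if (any(rs == 0))
    stop("count matrix has a zero row; run ergodic_trim() first")

  if (mode == "naive") {
    P <- C / rs
    e <- eigen(t(P))
    i1 <- which.min(abs(e$values - 1))
    pi <- Re(e$vectors[, i1])
    pi <- abs(pi) / sum(abs(pi))
    ev <- e$values[order(Mod(e$values), decreasing = TRUE)]
    # re-derive eigenvalues of P itself (same spectrum as t(P))
    eigenvalues <- ev
  } else {
    Csym <- C + t(C)
    x <- Csym / sum(Csym)
    for (it in seq_len(max_iter)) {
      xi <- rowSums(x)
      denom <- outer(rs / xi, rs / xi, "+")
      x_new <- ifelse(Csym > 0, Csym / denom, 0)
      x_new <- x_new / sum(x_new)
      delta <- max(abs(x_new - x))
      x <- x_new
      if (delta < tol) break
    }
    if (delta >= tol)
      stop(sprintf("reversible MLE did not converge: residual %.3e after %d sweeps",
                   delta, max_iter))
    pi <- rowSums(x)
    P <- x / pi
    # reversible P is similar to a symmetric matrix: real spectrum
    s <- sqrt(pi)
    A <- (s %o% (1 / s)) * P
    A <- (A + t(A)) / 2
    eigenvalues <- sort(eigen(A, symmetric = TRUE, only.values = TRUE)$values,
                        decreasing = TRUE)
  }

  model <- structure(list(P = P, pi = as.numeric(pi), eigenvalues = eigenvalues,
                          lag = counts$lag, mode = mode, K = counts$K,
                          mapping = counts$mapping %||% seq_len(counts$K)),
                     class = "TransitionModel")
  validate_transition_model(model)
  model
}

#' Assert the structural invariants of a transition model
#'
#' Checks row-stochasticity, positivity and normalization of the stationary
#' distribution, stationarity (`pi P = pi`), the unit leading eigenvalue,
#' and, for reversible estimates, detailed balance. Called automatically
#' after every estimate; exported for use on externally constructed models.
#'
#' @param model a `TransitionModel`.
#' @return the model, invisibly; stops on violation.
#' @export
validate_transition_model <- function(model) {
  P <- model$P; pi <- model$pi
  if (max(abs(rowSums(P) - 1)) > 1e-12 * max(1, ncol(P)))
    stop("transition matrix rows do not sum to 1")
  if (any(pi <= 0) || abs(sum(pi) - 1) > 1e-12 * max(1, length(pi)))
    stop("stationary distribution must be positive and sum to 1")
  if (max(abs(pi %*% P - pi)) > 1e-10)
    stop("pi is not stationary under P")
  if (abs(Mod(model$eigenvalues[1]) - 1) > 1e-10)
    stop("leading eigenvalue is not 1")
  if (model$mode == "reversible-mle") {
    db <- pi * P - t(pi * P)
    if (max(abs(db)) > 1e-10)
      stop("detailed balance violated in reversible estimate")
  }
  invisible(model)
}

#' @export
print.TransitionModel <- function(x, ...) {
  cat(sprintf("TransitionModel (%s): %d states, lag %g ns; top populations: %s\n",
              x$mode, x$K, x$lag,
              paste(sprintf("%.3f", utils::head(sort(x$pi, decreasing = TRUE), 3)),
                    collapse = ", ")))
  invisible(x)
}

#' Convenience: counts -> trim -> estimate in one call
#'
#' @inheritParams count_transitions
#' @inheritParams estimate_transition_matrix
#' @return a `TransitionModel` (see [estimate_transition_matrix()]).
#' @export
build_msm <- function(dtrajs, lag, spacing = 1, mode = "reversible-mle",
                      sliding = TRUE, n_states = NULL) {
  counts <- count_transitions(dtrajs, lag, spacing, sliding, n_states)
  estimate_transition_matrix(ergodic_trim(counts), mode = mode)
}

#' Implied timescales across lag times
#'
#' For each lag, estimates a transition model and converts its top
#' eigenvalues to implied relaxation timescales `t_i = -lag / log(mu_i)`
#' (and rates `k_i = 1/t_i`). Lag-independence of the timescales indicates
#' Markovian dynamics and guides lag-time selection. Eigenvalues outside
#' `(0, 1)` give no finite timescale and are flagged `"undefined"`; complex
#' eigenvalues (possible in naive mode) are flagged `"complex"` and their
#' modulus is used.
#'
#' @inheritParams count_transitions
#' @param lags numeric vector of lag times in ns.
#' @param mode estimator mode, as in [estimate_transition_matrix()].
#' @param n_timescales number of non-unit eigenvalues to report per lag
#'   (default `min(10, K - 1)`).
#' @return data frame of class `ImpliedTimescaleSpectrum` with columns
#'   `lag`, `index`, `eigenvalue` (modulus), `timescale` (ns), `rate`
#'   (1/ns), `flag`.
#' @export
implied_timescales <- function(dtrajs, lags, spacing = 1,
                               mode = "reversible-mle", sliding = TRUE,
                               n_timescales = 10L, n_states = NULL) {
  rows <- list()
  for (lag in lags) {
    res <- tryCatch({
      model <- build_msm(dtrajs, lag, spacing, mode, sliding, n_states)
      ev <- model$eigenvalues
      m <- min(n_timescales, model$K - 1L)
      if (m < 1L) stop("fewer than 2 states after trimming")
      ev_sub <- ev[seq_len(m) + 1L]   # skip the unit eigenvalue
      mod <- Mod(ev_sub)
      re <- Re(ev_sub)
      is_complex <- Mod(Im(ev_sub)) > 1e-12
      usable <- mod < 1 - 1e-12 & (is_complex | re > 1e-12)
      ts <- ifelse(usable, -lag / log(mod), NA_real_)
      flag <- ifelse(!usable, "undefined", ifelse(is_complex, "complex", "ok"))
      data.frame(lag = lag, index = seq_len(m), eigenvalue = mod,
                 timescale = ts, rate = 1 / ts, flag = flag,
                 stringsAsFactors = FALSE)
    }, error = function(e) {
      warning(sprintf("implied timescales at lag %g ns failed: %s",
                      lag, conditionMessage(e)), call. = FALSE)
      NULL
    })
    if (!is.null(res)) rows[[length(rows) + 1L]] <- res
  }
  out <- do.call(rbind, rows)
  class(out) <- c("ImpliedTimescaleSpectrum", "data.frame")
  out
}

#' Rank states by equilibrium population
#'
#' Orders the model's states by the maximum-likelihood equilibrium
#' population, descending (ties broken by state index). The top-ranked
#' state is the predicted binding pose.
#'
#' @param model a `TransitionModel`.
#' @param poses optional list of per-state representative poses or frames,
#'   indexed like the model states, carried into the output.
#' @return data frame with columns `rank`, `state` (model index),
#'   `orig_state` (index before ergodic trimming), `population`, and a
#'   `poses` attribute when given.
#' @export
rank_states <- function(model, poses = NULL) {
  ord <- order(-model$pi, seq_along(model$pi))
  out <- data.frame(rank = seq_along(ord), state = ord,
                    orig_state = model$mapping[ord],
                    population = model$pi[ord])
  if (!is.null(poses)) attr(out, "poses") <- poses[ord]
  out
}

#' Serialize a count or transition matrix as sparse text
#'
#' Writes a one-line JSON header (lag, K, mode/sliding) followed by
#' coordinate-format triplets `i j value` (1-based) for non-zero entries.
#'
#' @param x a `CountMatrix` or `TransitionModel`.
#' @param path output path.
#' @export
write_matrix_sparse <- function(x, path) {
  if (inherits(x, "CountMatrix")) {
    header <- jsonlite::toJSON(list(type = "counts", lag = x$lag, K = x$K,
                                    sliding = x$sliding), auto_unbox = TRUE)
    M <- x$C
  } else {
    header <- jsonlite::toJSON(list(type = "transition", lag = x$lag, K = x$K,
                                    mode = x$mode), auto_unbox = TRUE)
    M <- x$P
  }
  nz <- which(M != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(as.character(header), con)
  writeLines(sprintf("%d %d %.17g", nz[, 1], nz[, 2], M[nz]), con)
  invisible(path)
}

#' @rdname write_matrix_sparse
#' @return `read_matrix_sparse` returns a list with the dense `matrix` and
#'   the parsed `header`.
#' @export
read_matrix_sparse <- function(path) {
  lines <- readLines(path)
  header <- jsonlite::fromJSON(lines[1])
  M <- matrix(0, header$K, header$K)
  if (length(lines) > 1L) {
    toks <- strsplit(lines[-1], " ")
    for (tk in toks) M[as.integer(tk[1]), as.integer(tk[2])] <- as.numeric(tk[3])
  }
  list(matrix = M, header = header)
}
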