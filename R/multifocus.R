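#' Control-point focus set
#'
#' A set of M discrete target points with prescribed complex pressures, used
#' as the right-hand side of the beamforming system P = H U. Target phases
#' default to zero; supplying randomized phases can reduce inter-focus
#' interference.
#'
#' @param points M x 3 matrix (or length-3 vector) of control points, mm.
#' @param amplitudes target pressure magnitudes (recycled).
#' @param phases target phases in radians (recycled).
#' @return An object of class `focus_set`.
#' @export
focus_set <- function(points, amplitudes = 1, phases = 0) {
  points <- matrix(as.numeric(points), ncol = 3)
  m <- nrow(points)
  stopifnot(m >= 1)
  target <- rep_len(amplitudes, m) * exp(1i * rep_len(phases, m))
  structure(list(points = points, target_pressures = target),
            class = "focus_set")
}

# Resolve (H matrix, target vector) from the operator/focus-set objects or
# from bare matrix/vector arguments, so solvers work on synthetic systems too.
resolve_system <- function(H, targets) {
  Hm <- if (inherits(H, "propagation_operator")) H$matrix else as.matrix(H)
  P <- if (inherits(targets, "focus_set")) targets$target_pressures else as.complex(targets)
  if (nrow(Hm) != length(P))
    stop("H has ", nrow(Hm), " rows but ", length(P), " target pressures")
  list(H = Hm, P = P)
}

# Weighted minimum-norm interpolant U = W H^H (H W H^H)^{-1} P with Tikhonov
# fallback for rank-deficient Gram matrices (never silent).
weighted_pinv_solve <- function(Hm, P, w) {
  HWh <- w * Conj(t(Hm))            # N x M, rows scaled by w
  G <- Hm %*% HWh                   # M x M Gram matrix
  cond <- tryCatch(kappa(G, exact = TRUE), error = function(e) Inf)
  regularized <- FALSE
  coef <- tryCatch(solve(G, P), error = function(e) NULL)
  if (is.null(coef) || !all(is.finite(Mod(coef)))) {
    eps <- 1e-10 * Re(sum(diag(G))) / nrow(G)
    warning("rank-deficient Gram matrix; applying Tikhonov regularization eps = ",
            format(eps))
    coef <- solve(G + diag(eps, nrow(G)), P)
    regularized <- TRUE
  }
  U <- as.vector(HWh %*% coef)
  res <- sqrt(sum(Mod(Hm %*% U - P)^2)) / sqrt(sum(Mod(P)^2))
  list(U = U, residual = res, condition = cond, regularized = regularized)
}

#' Minimum-norm least-squares excitation
#'
#' Solves the underdetermined control-point system P = H U for the exact
#' interpolant of smallest Euclidean norm,
#' \deqn{\hat U = H^{*t} (H H^{*t})^{-1} P.}
#' With M < N and full row rank this reproduces the target pressures exactly;
#' the relative residual and Gram-matrix condition number are always part of
#' the result. A rank-deficient system falls back to a Tikhonov-regularized
#' solve with a warning.
#'
#' @param H a `propagation_operator` (or bare complex M x N matrix).
#' @param targets a [focus_set()] (or bare complex target vector).
#' @return list with `excitation` (complex N-vector), `residual`
#'   (\eqn{\|H\hat U - P\| / \|P\|}), `condition`, `regularized`.
#' @export
solve_min_norm <- function(H, targets) {
  s <- resolve_system(H, targets)
  r <- weighted_pinv_solve(s$H, s$P, rep(1, ncol(s$H)))
  list(excitation = r$U, residual = r$residual,
       condition = r$condition, regularized = r$regularized)
}

#' Iteratively weighted minimum-norm excitation
#'
#' Refines the minimum-norm solution with a diagonal weight matrix W,
#' \deqn{\hat U = W H^{*t} (H W H^{*t})^{-1} P,}
#' updating the weights by the amplitude-equalizing rule
#' \eqn{w_n \leftarrow w_n / \max(|u_n|, \epsilon)} (renormalized to mean 1)
#' so that power is spread more evenly across elements while every iterate
#' remains an exact interpolant of the control-point pressures. Iteration
#' stops when the largest relative change of any \eqn{|u_n|} drops below
#' `tol`, at `max_iter`, or — because extreme weights eventually
#' ill-condition the weighted Gram matrix — as soon as an iterate's relative
#' residual would exceed `resid_limit`, in which case the last exact iterate
#' is returned.
#'
#' @inheritParams solve_min_norm
#' @param max_iter maximum number of weight updates.
#' @param tol convergence tolerance on element amplitudes.
#' @param eps_floor amplitude floor in the weight update.
#' @param resid_limit largest acceptable relative residual of an iterate.
#' @return list with `excitation`, `weights`, `residual`, `condition`,
#'   `converged`, `iterations`, and a per-iteration `log` (residual and
#'   amplitude spread max|u|/min|u|).
#' @export
solve_weighted <- function(H, targets, max_iter = 50, tol = 1e-6,
                           eps_floor = 1e-12, resid_limit = 1e-8) {
  s <- resolve_system(H, targets)
  N <- ncol(s$H)
  w <- rep(1, N)
  r <- weighted_pinv_solve(s$H, s$P, w)
  amp <- Mod(r$U)
  log <- data.frame(iteration = 0L, residual = r$residual,
                    spread = max(amp) / max(min(amp), eps_floor))
  converged <- FALSE
  iters <- 0L
  if (max_iter > 0) {
    for (it in seq_len(max_iter)) {
      w_new <- w / pmax(amp, eps_floor)
      w_new <- w_new / mean(w_new)
      r_new <- weighted_pinv_solve(s$H, s$P, w_new)
      if (r_new$residual > resid_limit) break   # keep the last exact iterate
      amp_new <- Mod(r_new$U)
      delta <- max(abs(amp_new - amp) / pmax(amp, eps_floor))
      w <- w_new; r <- r_new; amp <- amp_new
      iters <- it
      log <- rbind(log, data.frame(iteration = it, residual = r$residual,
                                   spread = max(amp) / max(min(amp), eps_floor)))
      if (delta < tol) { converged <- TRUE; break }
    }
  } else converged <- TRUE
  list(excitation = r$U, weights = w, residual = r$residual,
       condition = r$condition, converged = converged,
       iterations = iters, log = log)
}

#' Export an excitation vector as CSV
#'
#' Columns: `element_id, amp, phase_rad`.
#' @param excitation complex vector.
#' @param path file path.
#' @export
write_excitation_csv <- function(excitation, path) {
  utils::write.csv(data.frame(element_id = seq_along(excitation),
                              amp = Mod(excitation),
                              phase_rad = Arg(excitation)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read a focus set from CSV
#'
#' Columns: `x_mm, y_mm, z_mm, amp, phase_rad` (amp/phase optional).
#' @param path file path.
#' @export
read_focus_set_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("x_mm", "y_mm", "z_mm")
  if (!all(need %in% names(df)))
    stop("focus-set CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  focus_set(as.matrix(df[, need]),
            amplitudes = if ("amp" %in% names(df)) df$amp else 1,
            phases = if ("phase_rad" %in% names(df)) df$phase_rad else 0)
}
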