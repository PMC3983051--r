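#' Rational switching function
#'
#' `s(r) = (1 - (r/r0)^n) / (1 - (r/r0)^m)` with `m > n`, the smooth contact
#' indicator used for differentiable collective variables. The removable
#' singularity at `r = r0` is handled by its limit value `n/m` (0.6 for the
#' default exponents 6/10). As the exponents grow (at fixed ratio) the
#' function approaches the sharp step `r < r0`.
#'
#' @param r distance(s), nm.
#' @param r0 switching distance, nm.
#' @param n,m exponents (defaults 6 and 10).
#' @export
switching_function <- function(r, r0, n = 6, m = 10) {
  x <- r / r0
  lx <- log(pmax(x, .Machine$double.xmin))
  out <- numeric(length(x))
  sing <- abs(x - 1) < 1e-9
  out[sing] <- n / m
  big <- !sing & m * lx > 700        # x^m would overflow: use the tail form
  out[big] <- exp((n - m) * lx[big])
  rest <- !sing & !big
  out[rest] <- (1 - x[rest]^n) / (1 - x[rest]^m)
  close <- !sing & abs(x - 1) < 1e-6
  if (any(close)) {
    # first-order expansion around the removable singularity at x = 1
    e <- x[close] - 1
    out[close] <- n / m + (n * (m - n)) / (2 * m^2) * e
  }
  out
}

#' Build the native-contact list of a reference structure
#'
#' All pairs of selected atoms on nucleotides separated by at least
#' `min_sep` in sequence (`|i - j| >= 2` by default, excluding trivially
#' bonded neighbours) whose distance in the reference is below `cutoff`.
#' Each pair is stored with its native distance; the fraction of these
#' contacts formed in a frame is the Q collective variable.
#'
#' @param native reference [g4_structure()].
#' @param roles atom roles eligible for contacts (default `c("O6", "N7",
#'   "N2")`, heavy atoms on the guanine Hoogsteen faces).
#' @param cutoff native-distance cutoff, nm.
#' @param min_sep minimum `|i - j|` nucleotide separation.
#' @param resno optional nucleotide subset (e.g. the 12 guanines).
#' @return A `g4_contacts` object: data.frame `pairs` with columns `resno_i`,
#'   `role_i`, `resno_j`, `role_j`, `native_distance`, plus `n_total`.
#' @export
build_native_contacts <- function(native, roles = c("O6", "N7", "N2"),
                                  cutoff = 0.45, min_sep = 2, resno = NULL) {
  X <- atom_coords(native, roles, resno = resno)
  rn <- attr(X, "resno"); rl <- attr(X, "role")
  n <- nrow(X)
  pr <- utils::combn(n, 2)
  i <- pr[1, ]; j <- pr[2, ]
  keep <- abs(rn[i] - rn[j]) >= min_sep
  d <- sqrt(rowSums((X[i, , drop = FALSE] - X[j, , drop = FALSE])^2))
  keep <- keep & d < cutoff
  # enforce i < j on nucleotide then role order
  ii <- i[keep]; jj <- j[keep]
  swap <- rn[ii] > rn[jj]
  tmp <- ii[swap]; ii[swap] <- jj[swap]; jj[swap] <- tmp
  pairs <- data.frame(resno_i = rn[ii], role_i = rl[ii],
                      resno_j = rn[jj], role_j = rl[jj],
                      native_distance = d[keep],
                      stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$resno_i, pairs$resno_j, pairs$role_i,
                       pairs$role_j), , drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(pairs = pairs, n_total = nrow(pairs),
                 roles = roles, cutoff = cutoff),
            class = "g4_contacts")
}

#' @export
print.g4_contacts <- function(x, ...) {
  cat(sprintf("g4_contacts: %d native contacts (roles %s, cutoff %.2f nm)\n",
              x$n_total, paste(x$roles, collapse = "/"), x$cutoff))
  invisible(x)
}

contact_distances <- function(structure, contacts) {
  p <- contacts$pairs
  di <- numeric(nrow(p))
  for (k in seq_len(nrow(p))) {
    a <- atom_coords(structure, p$role_i[k], resno = p$resno_i[k])
    b <- atom_coords(structure, p$role_j[k], resno = p$resno_j[k])
    di[k] <- sqrt(sum((a[1, ] - b[1, ])^2))
  }
  di
}

#' Fraction of native contacts (Q)
#'
#' In `sharp` mode a contact counts as formed when its current distance is
#' below `lambda` times its native distance (default `lambda = 1.2`); Q is
#' the formed fraction, in `[0, 1]`. In `smooth` mode each pair contributes
#' its rational switching value at `r0 = lambda * native_distance`, giving a
#' differentiable variant suitable for biasing.
#'
#' @param structure frame to evaluate.
#' @param contacts a `g4_contacts` from [build_native_contacts()].
#' @param mode `"sharp"` or `"smooth"`.
#' @param lambda contact tolerance factor on the native distance.
#' @param n,m smooth-mode switching exponents.
#' @return Q in `[0, 1]`.
#' @export
compute_q <- function(structure, contacts, mode = c("sharp", "smooth"),
                      lambda = 1.2, n = 6, m = 10) {
  mode <- match.arg(mode)
  if (is.null(contacts$pairs) || nrow(contacts$pairs) == 0)
    stopf("empty contact set")
  d <- contact_distances(structure, contacts)
  r0 <- lambda * contacts$pairs$native_distance
  if (mode == "sharp") mean(d < r0) else mean(switching_function(d, r0, n, m))
}

#' Cation-O6 coordination number (N_ion)
#'
#' Number of (ion, O6) pairs closer than `r0` (`sharp`), or the sum of
#' rational switching values (`smooth`). Zero ions give 0.
#'
#' @param structure frame carrying ion coordinates.
#' @param target_role acceptor atom role the cations coordinate (default
#'   `"O6"`, the guanine carbonyl oxygens lining the channel).
#' @param r0 coordination distance, nm (default 0.35).
#' @param mode `"sharp"` or `"smooth"`.
#' @param n,m smooth-mode switching exponents.
#' @export
compute_ion_coordination <- function(structure, target_role = "O6", r0 = 0.35,
                                     mode = c("sharp", "smooth"),
                                     n = 6, m = 10) {
  mode <- match.arg(mode)
  if (nrow(structure$ions) == 0) return(0)
  X <- atom_coords(structure, target_role, require = FALSE)
  if (nrow(X) == 0) return(0)
  d <- cross_dist(structure$ions, X)
  if (mode == "sharp") sum(d < r0) else sum(switching_function(d, r0, n, m))
}

#' Evaluate the four collective variables on one frame
#'
#' Computes the CV vector (Q, dRMSD, N_ion, Rg) that the bias-exchange
#' engine biases on: fraction of native guanine contacts, distance RMSD of
#' the `C4*` backbone with respect to the native structure, cation-O6
#' coordination number, and radius of gyration.
#'
#' @param structure frame to evaluate.
#' @param native native reference structure.
#' @param contacts native contacts from [build_native_contacts()].
#' @param config optional list overriding defaults: `q_mode`, `lambda`,
#'   `drmsd_roles`, `ion_r0`, `ion_mode`, `rg_roles`.
#' @return named list of class `g4_cv` with elements `q`, `drmsd`, `n_ion`,
#'   `rg`.
#' @export
evaluate_cv_vector <- function(structure, native, contacts, config = list()) {
  cf <- utils::modifyList(list(q_mode = "sharp", lambda = 1.2,
                               drmsd_roles = "C4*", ion_r0 = 0.35,
                               ion_mode = "sharp", rg_roles = "C4*"), config)
  out <- list(
    q = compute_q(structure, contacts, mode = cf$q_mode, lambda = cf$lambda),
    drmsd = compute_drmsd(structure, native, roles = cf$drmsd_roles),
    n_ion = compute_ion_coordination(structure, r0 = cf$ion_r0,
                                     mode = cf$ion_mode),
    rg = compute_rg(structure, roles = cf$rg_roles))
  class(out) <- "g4_cv"
  out
}

#' @export
print.g4_cv <- function(x, ...) {
  cat(sprintf("CV vector: Q = %.3f, dRMSD = %.4f nm, N_ion = %.2f, Rg = %.4f nm\n",
              x$q, x$drmsd, x$n_ion, x$rg))
  invisible(x)
}

#' Evaluate the CV vector along a trajectory
#'
#' @inheritParams evaluate_cv_vector
#' @param trajectory a [g4_trajectory()].
#' @return data.frame with columns `time_ns`, `q`, `drmsd_nm`, `n_ion`,
#'   `rg_nm` (the CSV stream layout).
#' @export
cv_trace <- function(trajectory, native, contacts, config = list()) {
  nf <- n_frames(trajectory)
  out <- data.frame(time_ns = trajectory$times, q = NA_real_,
                    drmsd_nm = NA_real_, n_ion = NA_real_, rg_nm = NA_real_)
  for (f in seq_len(nf)) {
    cv <- evaluate_cv_vector(get_frame(trajectory, f), native, contacts,
                             config)
    out[f, 2:5] <- c(cv$q, cv$drmsd, cv$n_ion, cv$rg)
  }
  out
}
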