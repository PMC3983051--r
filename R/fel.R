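#' Free-energy surface container
#'
#' Binned 1D or 2D free-energy values over named CV axes. Supported bins
#' (those with samples) have finite values with minimum 0; unsupported bins
#' are masked and excluded from every comparison.
#'
#' @param axes character vector of 1 or 2 CV names.
#' @param edges list of bin-edge vectors, one per axis.
#' @param values numeric vector (1D) or matrix (2D) of free energies,
#'   kJ/mol.
#' @param mask logical same shape as `values`; `TRUE` marks supported bins.
#' @return object of class `g4_fel`.
#' @export
fel <- function(axes, edges, values, mask = NULL) {
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  dims <- if (is.matrix(values)) dim(values) else length(values)
  if (!identical(as.integer(dims), as.integer(nb)))
    stopf("values shape (%s) does not match the bin counts (%s)",
          paste(dims, collapse = " x "), paste(nb, collapse = " x "))
  if (is.null(mask)) mask <- is.finite(values) & !is.na(values)
  if (any(mask)) values <- values - min(values[mask])
  values[!mask] <- NA_real_
  structure(list(axes = axes, edges = edges,
                 centers = lapply(edges, function(e)
                   (head(e, -1) + tail(e, -1)) / 2),
                 values = values, mask = mask),
            class = "g4_fel")
}

# 1D surface over an explicit point grid (used by the bias readout)
fel_1d <- function(centers, values, axis = "s") {
  n <- length(centers)
  half <- if (n > 1) diff(centers) / 2 else 0.5
  edges <- c(centers[1] - half[1], centers[-n] + half,
             centers[n] + half[length(half)])
  fel(axis, list(edges), values)
}

#' @export
print.g4_fel <- function(x, ...) {
  cat(sprintf("g4_fel over (%s): %s bins, %d supported, range %.2f kJ/mol\n",
              paste(x$axes, collapse = ", "),
              paste(vapply(x$centers, length, 1L), collapse = " x "),
              sum(x$mask), max(x$values[x$mask]) - min(x$values[x$mask])))
  invisible(x)
}

#' Histogram free-energy estimate from unbiased samples
#'
#' `F_bin = -kB T ln(count_bin / max_count)`: the Boltzmann inversion of the
#' sample histogram, used on neutral-replica samples (no reweighting of
#' biased replicas is attempted). Empty bins are masked; the minimum over
#' supported bins is 0 by construction. An initial `equil_frac` of the
#' samples is discarded as equilibration.
#'
#' @param samples numeric vector (1D) or matrix/data.frame with one column
#'   per CV axis, in time order.
#' @param axes CV names (default `"cv1"`, `"cv2"`).
#' @param bins bin count per axis (recycled; default 40) or a list of
#'   explicit edge vectors.
#' @param range optional list of `c(lo, hi)` per axis; default the observed
#'   range padded by 5%.
#' @param temperature K.
#' @param equil_frac fraction of initial samples discarded (default 0.2).
#' @param min_count bins with fewer samples than this are treated as
#'   unsupported (default 1; raise it to suppress barely-visited bins at
#'   the sparse high-free-energy edge of the sampled region, e.g. before
#'   basin identification).
#' @return a [fel()] object.
#' @export
estimate_fel <- function(samples, axes = NULL, bins = 40, range = NULL,
                         temperature = 300, equil_frac = 0.2,
                         min_count = 1) {
  X <- as.matrix(samples)
  d <- ncol(X)
  if (!d %in% 1:2) stopf("estimate_fel supports 1 or 2 CV axes")
  if (is.null(axes)) axes <- paste0("cv", seq_len(d))
  n0 <- nrow(X)
  X <- X[seq_len(n0) > floor(equil_frac * n0), , drop = FALSE]
  if (nrow(X) < 1) stopf("no samples left after equilibration discard")
  if (is.list(bins)) {
    edges <- bins
  } else {
    bins <- rep_len(bins, d)
    edges <- vector("list", d)
    for (j in seq_len(d)) {
      r <- if (!is.null(range)) range[[j]] else {
        rr <- base::range(X[, j]); pad <- 0.05 * max(diff(rr), 1e-12)
        c(rr[1] - pad, rr[2] + pad)
      }
      edges[[j]] <- seq(r[1], r[2], length.out = bins[j] + 1)
    }
  }
  idx <- lapply(seq_len(d), function(j) {
    i <- findInterval(X[, j], edges[[j]], rightmost.closed = TRUE)
    i[i < 1 | i > length(edges[[j]]) - 1] <- NA
    i
  })
  nb <- vapply(edges, function(e) length(e) - 1L, 1L)
  keep <- Reduce(`&`, lapply(idx, function(i) !is.na(i)))
  if (!any(keep)) stopf("all samples fall outside the binning range")
  counts <- if (d == 1) {
    tabulate(idx[[1]][keep], nbins = nb[1])
  } else {
    m <- matrix(0L, nb[1], nb[2])
    t2 <- table(factor(idx[[1]][keep], levels = seq_len(nb[1])),
                factor(idx[[2]][keep], levels = seq_len(nb[2])))
    m[] <- as.integer(t2)
    m
  }
  vals <- -kB * temperature * log(counts / max(counts))
  vals[counts < min_count] <- NA_real_
  fel(axes, edges, vals, mask = counts >= max(1, min_count))
}

#' RMS difference between two free-energy surfaces
#'
#' RMS of `F_a - F_b` over bins supported in both surfaces, after re-aligning
#' each surface's minimum over the common support to zero. The convergence
#' diagnostic used to compare surfaces estimated from independent neutral
#' replicas (or run halves).
#'
#' @param fel_a,fel_b [fel()] objects with identical bin specifications.
#' @return RMS difference in kJ/mol.
#' @export
fel_rms_difference <- function(fel_a, fel_b) {
  if (!identical(fel_a$edges, fel_b$edges))
    stopf("free-energy surfaces have mismatched bins")
  common <- fel_a$mask & fel_b$mask
  if (!any(common)) stopf("no commonly supported bins")
  a <- fel_a$values[common] - min(fel_a$values[common])
  b <- fel_b$values[common] - min(fel_b$values[common])
  sqrt(mean((a - b)^2))
}

# neighbours of linear index k on the (n1 x n2) grid graph
grid_neighbours <- function(k, n1, n2) {
  if (is.na(n2)) {  # 1D
    c(if (k > 1) k - 1, if (k < n1) k + 1)
  } else {
    i <- (k - 1) %% n1 + 1; j <- (k - 1) %/% n1 + 1
    out <- integer(0)
    if (i > 1) out <- c(out, k - 1)
    if (i < n1) out <- c(out, k + 1)
    if (j > 1) out <- c(out, k - n1)
    if (j < n2) out <- c(out, k + n1)
    out
  }
}

#' Identify basins of attraction on a free-energy surface
#'
#' Each supported bin is assigned by steepest descent over the grid graph
#' (2 neighbours in 1D, 4 in 2D) to a local minimum; minima whose separating
#' saddle lies less than `min_barrier` above the shallower minimum are then
#' merged (persistence criterion), so shallow statistical ripple does not
#' split basins. Basins are numbered by ascending minimum free energy, ties
#' broken by bin index.
#'
#' @param fel a [fel()] object.
#' @param min_barrier minimum separating barrier to keep two basins
#'   distinct, kJ/mol (default `1 kB T` at 300 K).
#' @return object of class `g4_basins`: `labels` (basin id per bin, NA for
#'   unsupported), `minima` (data.frame bin, value), `n_basins`, and the
#'   parent surface's axes/edges.
#' @export
identify_basins <- function(fel, min_barrier = kB * 300) {
  v <- fel$values
  n1 <- length(fel$centers[[1]])
  n2 <- if (length(fel$centers) == 2) length(fel$centers[[2]]) else NA
  nk <- length(v)
  sup <- which(fel$mask)
  if (length(sup) == 0) stopf("surface has no supported bins")
  # steepest descent with memoisation
  root <- rep(NA_integer_, nk)
  descend <- function(k) {
    path <- integer(0)
    while (is.na(root[k])) {
      path <- c(path, k)
      nb <- grid_neighbours(k, n1, n2)
      nb <- nb[fel$mask[nb]]
      if (length(nb) == 0) { root[path] <<- k; break }
      best <- nb[which.min(v[nb])]
      if (v[best] < v[k] ||
          (v[best] == v[k] && best < k)) k <- best
      else { root[path] <<- k; break }
    }
    if (length(path) > 0 && !is.na(root[k])) root[path] <<- root[k]
    root[path[1]]
  }
  for (k in sup) if (is.na(root[k])) descend(k)
  minima <- sort(unique(root[sup]))
  lab <- match(root, minima)
  # pairwise saddles between adjacent basins
  nmin <- length(minima)
  saddle <- matrix(Inf, nmin, nmin)
  for (k in sup) {
    nb <- grid_neighbours(k, n1, n2)
    nb <- nb[fel$mask[nb] & nb > k]
    for (q in nb) {
      a <- lab[k]; b <- lab[q]
      if (a != b) {
        h <- max(v[k], v[q])
        if (h < saddle[a, b]) saddle[a, b] <- saddle[b, a] <- h
      }
    }
  }
  # persistence merging
  group <- seq_len(nmin)
  minF <- v[minima]
  repeat {
    gs <- unique(group)
    if (length(gs) < 2) break
    best <- NULL; bestp <- Inf
    for (ai in seq_along(gs)) for (bi in seq_along(gs)) {
      if (bi <= ai) next
      a <- gs[ai]; b <- gs[bi]
      sa <- min(saddle[group == a, group == b, drop = FALSE])
      if (!is.finite(sa)) next
      shallow <- max(min(minF[group == a]), min(minF[group == b]))
      p <- sa - shallow
      if (p < bestp) { bestp <- p; best <- c(a, b) }
    }
    if (is.null(best) || bestp >= min_barrier) break
    a <- best[1]; b <- best[2]
    deeper <- if (min(minF[group == a]) <= min(minF[group == b])) a else b
    other <- if (deeper == a) b else a
    group[group == other] <- deeper
  }
  # one retained minimum (the deepest, ties by bin index) per merged group
  gs <- unique(group)
  kept <- vapply(gs, function(g) {
    cand <- minima[group == g]
    as.integer(cand[order(v[cand], cand)][1])
  }, integer(1))
  ord <- order(v[kept], kept)
  kept <- kept[ord]; gs <- gs[ord]
  final <- rep(NA_integer_, nk)
  for (gi in seq_along(gs)) final[lab %in% which(group == gs[gi])] <- gi
  final[!fel$mask] <- NA_integer_
  labels <- final
  if (!is.na(n2)) labels <- matrix(labels, n1, n2)
  mdf <- data.frame(bin = kept, value = v[kept])
  if (!is.na(n2)) {
    mdf$i <- (kept - 1) %% n1 + 1
    mdf$j <- (kept - 1) %/% n1 + 1
  } else mdf$i <- kept
  structure(list(labels = labels, minima = mdf, n_basins = length(kept),
                 axes = fel$axes, edges = fel$edges),
            class = "g4_basins")
}

#' @export
print.g4_basins <- function(x, ...) {
  cat(sprintf("g4_basins: %d basins; minima at F = %s kJ/mol\n", x$n_basins,
              paste(sprintf("%.2f", x$minima$value), collapse = ", ")))
  invisible(x)
}

#' Assign frames to basins by their CV values
#'
#' Each frame is labelled by the basin of its containing bin; frames outside
#' the binning range or in unsupported bins are `NA` (unassigned).
#'
#' @param cvs numeric vector (1D) or matrix (frames x axes) of CV values.
#' @param basins a [identify_basins()] result.
#' @return integer vector of basin labels (NA = unassigned).
#' @export
assign_frames <- function(cvs, basins) {
  X <- as.matrix(cvs)
  d <- length(basins$edges)
  if (ncol(X) != d) stopf("CV columns do not match the surface axes")
  idx <- lapply(seq_len(d), function(j) {
    i <- findInterval(X[, j], basins$edges[[j]], rightmost.closed = TRUE)
    i[i < 1 | i > length(basins$edges[[j]]) - 1] <- NA
    i
  })
  n1 <- length(basins$edges[[1]]) - 1
  lin <- if (d == 1) idx[[1]] else (idx[[2]] - 1) * n1 + idx[[1]]
  out <- rep(NA_integer_, nrow(X))
  ok <- !is.na(lin)
  out[ok] <- basins$labels[lin[ok]]
  out
}
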