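#' Acceleration band scheme
#'
#' Defines the partition of the acceleration (ENMO) axis into intensity bands.
#' Bands are half-open, lower-inclusive intervals \code{[lo, hi)}; the last
#' band is unbounded above (\code{[lo, Inf)}).
#'
#' @param edges Strictly increasing lower band edges in mg, starting at 0.
#'   The default gives the nine-band intensity spectrum: 50 mg increments up
#'   to 350 mg, then 350-700 mg and >= 700 mg.
#' @param labels Optional band labels; defaults to \code{"0-50"}, ...,
#'   \code{"700+"} style labels built from the edges.
#' @return An object of class \code{band_scheme}: a list with \code{edges}
#'   (lower edges), \code{upper} (upper edges, last \code{Inf}) and
#'   \code{labels}.
#' @examples
#' sch <- band_scheme()
#' sch$labels
#' @export
band_scheme <- function(edges = c(0, 50, 100, 150, 200, 250, 300, 350, 700),
                        labels = NULL) {
  if (length(edges) < 3L) stop("a band scheme needs at least 3 bands")
  if (edges[1L] != 0) stop("the first band edge must be 0")
  if (any(diff(edges) <= 0)) stop("band edges must be strictly increasing")
  upper <- c(edges[-1L], Inf)
  if (is.null(labels)) {
    labels <- ifelse(is.finite(upper),
                     paste0(edges, "-", upper),
                     paste0(edges, "+"))
  }
  if (length(labels) != length(edges)) {
    stop("labels must have one entry per band")
  }
  structure(list(edges = edges, upper = upper, labels = labels),
            class = "band_scheme")
}

#' @export
print.band_scheme <- function(x, ...) {
  cat("Acceleration band scheme (", length(x$edges), " bands, mg):\n", sep = "")
  cat(" ", paste(x$labels, collapse = ", "), "\n")
  invisible(x)
}

#' Close a composition to a fixed total
#'
#' Linearly rescales non-negative parts so they sum to \code{total} (closure
#' in the Aitchison-geometry sense). Order and relative information are
#' preserved.
#'
#' @param parts Numeric vector (or matrix with one composition per row) of
#'   non-negative durations.
#' @param total Closure constant; 960 min for the 07:00-23:00 waking day.
#' @return Rescaled parts of the same shape, summing (row-wise) to
#'   \code{total}.
#' @examples
#' close_composition(c(1, 2, 3), total = 60)
#' @export
close_composition <- function(parts, total = 960) {
  if (total <= 0) stop("total must be positive")
  if (is.matrix(parts)) {
    s <- rowSums(parts)
    if (any(s <= 0)) stop("cannot close an all-zero composition (row sum 0)")
    return(parts * (total / s))
  }
  s <- sum(parts)
  if (s <= 0) stop("cannot close an all-zero composition")
  parts * (total / s)
}

#' Replace zero parts with a pseudo-duration
#'
#' Compositional log-ratio transforms require strictly positive parts. Bands
#' in which a participant accumulated no time are given a small
#' pseudo-duration before closure. The default of 1/120 min (0.5 s) is far
#' below the 1-min resolution at which band minutes are reported.
#'
#' @param parts Numeric vector or matrix of non-negative durations.
#' @param pseudo Pseudo-duration in minutes added to zero parts.
#' @return Parts with zeros replaced; positive parts are untouched.
#' @export
zero_replace <- function(parts, pseudo = 1 / 120) {
  if (pseudo <= 0) stop("pseudo must be positive")
  parts[parts == 0] <- pseudo
  parts
}

check_positive <- function(x, labels = NULL) {
  bad <- which(!(x > 0))
  if (length(bad)) {
    lab <- if (!is.null(labels)) labels[bad] else
      if (!is.null(names(x))) names(x)[bad] else as.character(bad)
    stop("non-positive part(s) in composition: ", paste(lab, collapse = ", "),
         "; replace zeros (see zero_replace) before transforming")
  }
  invisible(TRUE)
}

#' Centred log-ratio transform
#'
#' \code{clr_j = log(x_j) - mean_k log(x_k)}. Coordinates sum to zero; the
#' transform is invariant to closure.
#'
#' @param x Strictly positive composition (vector, or matrix with one
#'   composition per row).
#' @return clr coordinates of the same shape.
#' @seealso [clr_inverse()], [pivot_ilr()]
#' @export
clr <- function(x) {
  if (is.matrix(x)) {
    if (any(!(x > 0))) {
      bad <- which(colSums(!(x > 0)) > 0)
      lab <- if (!is.null(colnames(x))) colnames(x)[bad] else as.character(bad)
      stop("non-positive part(s) in composition: ", paste(lab, collapse = ", "))
    }
    lx <- log(x)
    return(lx - rowMeans(lx))
  }
  check_positive(x)
  lx <- log(x)
  lx - mean(lx)
}

#' Inverse centred log-ratio transform
#'
#' @param z clr coordinates (vector or row matrix).
#' @param total Closure constant for the returned composition.
#' @return The unique composition closed to \code{total} whose clr image is
#'   \code{z} (up to the additive constant clr discards).
#' @export
clr_inverse <- function(z, total = 960) {
  close_composition(exp(z), total = total)
}

#' Pivot-coordinate ILR basis
#'
#' Builds the sequential-binary-partition basis whose first coordinate
#' contrasts one designated part (the lead) against the geometric mean of all
#' remaining parts. Coordinate k contrasts the part at position k of the
#' pivot order against the geometric mean of the parts after it.
#'
#' The regression use of these bases is the "rotation": refitting the same
#' model with each band in turn as the lead isolates that band's first pivot
#' coordinate, whose coefficient measures the band relative to all others.
#'
#' @param D Number of parts (>= 3).
#' @param lead Index (1..D) of the part isolated by the first coordinate.
#' @param order Optional permutation of the remaining indices; default is the
#'   original order with the lead moved to the front. The first coordinate is
#'   provably invariant to this ordering.
#' @return An object of class \code{pivot_basis}: list with \code{D},
#'   \code{lead}, \code{perm} (full pivot order) and \code{V}, the D x (D-1)
#'   matrix with orthonormal columns such that \code{ilr = t(V) \%*\% clr(x)}.
#' @examples
#' b <- pivot_basis(4, lead = 2)
#' crossprod(b$V)  # identity
#' @export
pivot_basis <- function(D, lead = 1L, order = NULL) {
  if (D < 3L) stop("D must be at least 3")
  lead <- as.integer(lead)
  if (lead < 1L || lead > D) stop("lead must be in 1..D")
  rest <- setdiff(seq_len(D), lead)
  if (is.null(order)) order <- rest
  if (!setequal(order, rest) || length(order) != D - 1L) {
    stop("order must be a permutation of the non-lead indices")
  }
  perm <- c(lead, as.integer(order))
  # contrast matrix in pivot order: column k isolates position k against
  # the positions after it
  V <- matrix(0, nrow = D, ncol = D - 1L)
  for (k in seq_len(D - 1L)) {
    nk <- D - k
    V[k, k] <- sqrt(nk / (nk + 1))
    V[(k + 1L):D, k] <- -1 / sqrt(nk * (nk + 1))
  }
  # map rows back to original part indices
  V <- V[order(perm), , drop = FALSE]
  structure(list(D = D, lead = lead, perm = perm, V = V),
            class = "pivot_basis")
}

#' @export
print.pivot_basis <- function(x, ...) {
  cat("Pivot ILR basis: D =", x$D, ", lead part =", x$lead, "\n")
  invisible(x)
}

#' Pivot-coordinate ILR transform
#'
#' Maps a strictly positive D-part composition to D-1 isometric log-ratio
#' coordinates. The first coordinate is
#' \code{z_1 = sqrt((D-1)/D) * log(x_lead / gm(remaining))}, i.e. the lead
#' part against the geometric mean of all others, and equals
#' \code{sqrt(D/(D-1)) * clr_lead}.
#'
#' @param x Composition vector, or matrix with one composition per row.
#' @param basis A [pivot_basis()]; defaults to lead = 1 for the width of
#'   \code{x}.
#' @return Numeric vector (or matrix) of D-1 ilr coordinates.
#' @export
pivot_ilr <- function(x, basis = NULL) {
  D <- if (is.matrix(x)) ncol(x) else length(x)
  if (is.null(basis)) basis <- pivot_basis(D)
  if (basis$D != D) stop("basis dimension does not match composition")
  z <- clr(x)
  if (is.matrix(z)) z %*% basis$V else drop(t(basis$V) %*% z)
}

#' Inverse pivot-coordinate ILR transform
#'
#' @param z D-1 ilr coordinates (vector or row matrix).
#' @param basis The [pivot_basis()] that produced \code{z}.
#' @param total Closure constant of the returned composition.
#' @return The unique composition closed to \code{total} mapping to \code{z}.
#' @export
pivot_ilr_inverse <- function(z, basis, total = 960) {
  if (is.matrix(z)) {
    if (ncol(z) != basis$D - 1L) stop("coordinate dimension mismatch")
    return(clr_inverse(z %*% t(basis$V), total = total))
  }
  if (length(z) != basis$D - 1L) stop("coordinate dimension mismatch")
  clr_inverse(drop(basis$V %*% z), total = total)
}

#' Geometric-mean composition of a sample
#'
#' Component-wise geometric mean across compositions, closed to the common
#' total. This is the compositional centre: the minimiser of summed squared
#' Aitchison distances to the sample.
#'
#' @param X Matrix with one strictly positive composition per row.
#' @param total Closure constant.
#' @return A single closed composition (named as the columns of \code{X}).
#' @export
gmean_composition <- function(X, total = 960) {
  if (!is.matrix(X)) X <- matrix(X, nrow = 1)
  if (nrow(X) < 1L) stop("empty sample of compositions")
  if (any(!(X > 0))) stop("all compositions must be strictly positive")
  g <- exp(colMeans(log(X)))
  close_composition(g, total = total)
}

#' Variation matrix of a compositional sample
#'
#' Entry (i, j) is the sample variance of \code{log(x_i / x_j)} across the
#' sample: the canonical description of compositional spread. Symmetric with
#' a zero diagonal.
#'
#' @param X Matrix with one strictly positive composition per row (n >= 2).
#' @return D x D variation matrix.
#' @export
variation_matrix <- function(X) {
  if (!is.matrix(X) || nrow(X) < 2L) {
    stop("variation matrix needs at least 2 compositions")
  }
  if (any(!(X > 0))) stop("all compositions must be strictly positive")
  L <- log(X)
  D <- ncol(L)
  V <- matrix(0, D, D, dimnames = list(colnames(X), colnames(X)))
  for (i in seq_len(D - 1L)) {
    for (j in (i + 1L):D) {
      v <- stats::var(L[, i] - L[, j])
      V[i, j] <- v
      V[j, i] <- v
    }
  }
  V
}

#' One-for-remaining time reallocation
#'
#' Adds \code{minutes} to one band and removes \code{minutes / (D - 1)} from
#' each remaining band (negative \code{minutes} reverses the direction). The
#' total is conserved exactly. This is the reallocation underlying
#' one-for-remaining isotemporal substitution.
#'
#' @param x Composition vector (named or not).
#' @param band Band index or name receiving the time.
#' @param minutes Signed reallocation in minutes.
#' @return The reallocated composition.
#' @examples
#' x <- close_composition(rep(1, 9), 960)
#' reallocate(x, 9, 5)
#' @export
reallocate <- function(x, band, minutes) {
  j <- resolve_band(x, band)
  D <- length(x)
  out <- x - minutes / (D - 1)
  out[j] <- x[j] + minutes
  bad <- which(out <= 0)
  if (length(bad)) {
    lab <- if (!is.null(names(x))) names(x)[bad] else as.character(bad)
    stop("reallocation of ", minutes, " min drives band(s) ",
         paste(lab, collapse = ", "), " to zero or below")
  }
  out
}

resolve_band <- function(x, band) {
  if (is.character(band)) {
    if (is.null(names(x))) stop("composition has no band names")
    j <- match(band, names(x))
    if (is.na(j)) stop("unknown band: ", band)
    return(j)
  }
  j <- as.integer(band)
  if (j < 1L || j > length(x)) stop("band index out of range")
  j
}

#' Read / write composition CSV
#'
#' One row per participant; columns are the band labels, values in min/day.
#' A header row is mandatory.
#'
#' @param file Path to a CSV file.
#' @param id_col Optional id column name present in the file (kept as
#'   rownames on read, written as first column on write).
#' @return \code{read_compositions}: a numeric matrix of compositions.
#' @export
read_compositions <- function(file, id_col = NULL) {
  df <- utils::read.csv(file, check.names = FALSE)
  if (!is.null(id_col) && id_col %in% names(df)) {
    rn <- as.character(df[[id_col]])
    df[[id_col]] <- NULL
    m <- as.matrix(df)
    rownames(m) <- rn
  } else {
    m <- as.matrix(df)
  }
  storage.mode(m) <- "double"
  m
}

#' @rdname read_compositions
#' @param X Matrix of compositions (band labels as column names).
#' @export
write_compositions <- function(X, file, id_col = NULL) {
  df <- as.data.frame(X, check.names = FALSE)
  if (!is.null(id_col)) {
    df <- cbind(stats::setNames(data.frame(rownames(X)), id_col), df)
  }
  utils::write.csv(df, file, row.names = FALSE)
  invisible(file)
}
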