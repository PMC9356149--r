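#' Spherical-spline settings
#'
#' @param legendre_order number of Legendre terms in the spline kernel
#'   (default 7).
#' @param stiffness_m spline stiffness exponent (default 4, the standard
#'   choice for scalp potentials).
#' @param regularization value added to the diagonal of the spline system
#'   (default 1e-5).
#' @return list of class \code{SplineSettings}.
#' @export
splineSettings <- function(legendre_order = 7, stiffness_m = 4,
                           regularization = 1e-5) {
  stopifnot(legendre_order >= 1, stiffness_m >= 2)
  structure(list(legendre_order = legendre_order, stiffness_m = stiffness_m,
                 regularization = regularization),
            class = "SplineSettings")
}

# Legendre polynomials P_1..P_nmax at x, by the three-term recurrence;
# returns a length(x) x nmax matrix.
legendreP <- function(x, nmax) {
  out <- matrix(0, length(x), nmax)
  pm1 <- rep(1, length(x))       # P_0
  p <- x                         # P_1
  out[, 1] <- p
  if (nmax >= 2) for (n in 2:nmax) {
    pn <- ((2 * n - 1) * x * p - (n - 1) * pm1) / n
    out[, n] <- pn
    pm1 <- p; p <- pn
  }
  out
}

# spline kernel g(cos theta) = (1/4pi) sum_n (2n+1) / (n (n+1))^m P_n(cos theta)
splineG <- function(cosTheta, order, m) {
  n <- seq_len(order)
  w <- (2 * n + 1) / (n * (n + 1))^m
  P <- legendreP(pmin(pmax(cosTheta, -1), 1), order)
  as.vector(P %*% w) / (4 * pi)
}

unitRows <- function(mat) {
  nr <- sqrt(rowSums(mat^2))
  if (any(nr < 1e-12)) stop("geometry error: electrode at origin")
  mat / nr
}

#' Spherical-spline interpolation of scalp potentials
#'
#' Electrode positions are projected to the unit sphere; the spline system
#' with kernel \code{g(cos theta) = (1/4pi) sum_n (2n+1)/(n(n+1))^m P_n} is
#' solved with \code{regularization} added to the diagonal, and the target
#' locations are estimated per timepoint.  The estimate is linear in the
#' data and reproduces constant fields exactly.
#'
#' @param data matrix, good channels x samples.
#' @param goodPos matrix, good channels x 3 positions.
#' @param targetPos matrix, target channels x 3 positions.
#' @param settings a [splineSettings()].
#' @return matrix, target channels x samples.
#' @export
sphericalSplineInterpolate <- function(data, goodPos, targetPos,
                                       settings = splineSettings()) {
  data <- as.matrix(data)
  goodPos <- unitRows(as.matrix(goodPos))
  targetPos <- unitRows(matrix(as.matrix(targetPos), ncol = 3))
  ng <- nrow(goodPos)
  if (ng < 4) stop("geometry error: need at least 4 good channels")
  G <- matrix(splineG(tcrossprod(goodPos), settings$legendre_order,
                      settings$stiffness_m), ng, ng)
  G <- G + diag(settings$regularization, ng)
  A <- rbind(cbind(G, 1), c(rep(1, ng), 0))
  sol <- tryCatch(solve(A, rbind(data, 0)),
                  error = function(e) stop("geometry error: singular spline system"))
  Gt <- matrix(splineG(tcrossprod(targetPos, goodPos),
                       settings$legendre_order, settings$stiffness_m),
               nrow(targetPos), ng)
  Gt %*% sol[seq_len(ng), , drop = FALSE] +
    matrix(sol[ng + 1, ], nrow(targetPos), ncol(data), byrow = TRUE)
}

montagePositions <- function(rec, labels) {
  if (!nrow(rec@montage)) stop("geometry error: montage required")
  idx <- match(labels, rec@montage$label)
  as.matrix(rec@montage[idx, c("x", "y", "z")])
}

#' Interpolate whole-recording bad channels in place
#'
#' Replaces the data of the listed channels with their spherical-spline
#' estimate from all remaining channels.
#'
#' @param rec an [EEGRecording-class] with a montage.
#' @param badLabels channels to reconstruct.
#' @param settings a [splineSettings()].
#' @return the repaired [EEGRecording-class].
#' @export
interpolateBadChannels <- function(rec, badLabels,
                                   settings = splineSettings()) {
  if (!length(badLabels)) return(rec)
  good <- setdiff(rec@labels, badLabels)
  est <- sphericalSplineInterpolate(rec@data[good, , drop = FALSE],
                                    montagePositions(rec, good),
                                    montagePositions(rec, badLabels),
                                    settings)
  rec@data[match(badLabels, rec@labels), ] <- est
  addProvenance(rec, "interpolate_bad_channels", list(channels = badLabels))
}

#' Re-reference a recording
#'
#' Subtracts the mean over all channels (average reference) or over a named
#' subset from every channel.  When \code{recover_prior} is TRUE and the
#' prior online reference is known, a zero channel named after it is appended
#' before subtraction, so its signal is recovered in the new reference frame.
#'
#' @param rec an [EEGRecording-class].
#' @param mode \code{"average"} or \code{"subset"}.
#' @param subset_names channel names used as the new reference when
#'   \code{mode = "subset"}.
#' @param recover_prior append and recover the prior reference channel.
#' @return the re-referenced [EEGRecording-class].
#' @export
rereference <- function(rec, mode = c("average", "subset"),
                        subset_names = character(0), recover_prior = FALSE) {
  mode <- match.arg(mode)
  if (recover_prior && !identical(rec@reference, "unknown") &&
      !(rec@reference %in% rec@labels)) {
    rec@labels <- c(rec@labels, rec@reference)
    rec@data <- rbind(rec@data, 0)
    rownames(rec@data) <- rec@labels
    if (nrow(rec@montage))
      rec@montage <- rbind(rec@montage,
                           data.frame(label = rec@reference, x = NA_real_,
                                      y = NA_real_, z = NA_real_))
  }
  if (mode == "subset") {
    unknown <- setdiff(subset_names, rec@labels)
    if (length(unknown))
      stop("selection error: unknown channel(s): ",
           paste(unknown, collapse = ", "))
    refSig <- colMeans(rec@data[rec@labels %in% subset_names, , drop = FALSE])
  } else {
    refSig <- colMeans(rec@data)
  }
  out <- sweep(rec@data, 2, refSig, "-")
  setRecData(rec, out, "rereference",
             list(mode = mode, subset = subset_names,
                  recovered = recover_prior))
}
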