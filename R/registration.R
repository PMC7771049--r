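# Rigid-body pose parameterization, transform algebra, trial-set I/O and
# the "geometric centre" gold standard over repeated registrations.

#' @describeIn RigidParams-class Translation (tx, ty, tz) in mm.
#' @param x Object.
#' @export
setMethod("translation", "RigidParams", function(x) x@translation)

#' @describeIn RigidParams-class Rotation (rx, ry, rz) in degrees.
#' @export
setMethod("rotationAngles", "RigidParams", function(x) x@rotation)

setMethod("show", "RigidParams", function(object) {
  cat(sprintf("RigidParams: t = (%s) mm, r = (%s) deg\n",
              paste(signif(object@translation, 5), collapse = ", "),
              paste(signif(object@rotation, 5), collapse = ", ")))
})

#' @describeIn RigidTransform-class The 4x4 homogeneous matrix.
#' @param x Object.
#' @export
setMethod("transformMatrix", "RigidTransform", function(x) x@matrix)

setMethod("show", "RigidTransform", function(object) {
  cat("RigidTransform:\n")
  print(signif(object@matrix, 6))
})

#' @describeIn TrialSet-class The list of trial poses.
#' @param x Object.
#' @export
setMethod("trials", "TrialSet", function(x) x@trials)

setMethod("show", "TrialSet", function(object) {
  cat(sprintf("TrialSet '%s': %d trials\n", object@label,
              length(object@trials)))
})

rotX <- function(a) {
  a <- deg2rad(a)
  matrix(c(1, 0, 0, 0, cos(a), sin(a), 0, -sin(a), cos(a)), 3, 3)
}
rotY <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), 0, -sin(a), 0, 1, 0, sin(a), 0, cos(a)), 3, 3)
}
rotZ <- function(a) {
  a <- deg2rad(a)
  matrix(c(cos(a), sin(a), 0, -sin(a), cos(a), 0, 0, 0, 1), 3, 3)
}

#' Convert six pose parameters to a homogeneous transform
#'
#' The matrix is `Translate(t) o Rz(rz) o Ry(ry) o Rx(rx)`: right-handed
#' rotations about the world axes at the origin, applied x-first, then the
#' translation. This fixed convention stands in for the (undocumented)
#' workstation convention; any fixed choice preserves the error
#' statistics.
#'
#' @param p A [RigidParams-class].
#' @return A [RigidTransform-class].
#' @export
paramsToTransform <- function(p) {
  stopifnot(is(p, "RigidParams"))
  r <- p@rotation
  m <- diag(4)
  m[1:3, 1:3] <- rotZ(r[3]) %*% rotY(r[2]) %*% rotX(r[1])
  m[1:3, 4] <- p@translation
  new("RigidTransform", matrix = m)
}

#' Invert a rigid transform
#'
#' @param transform A [RigidTransform-class].
#' @return The inverse [RigidTransform-class].
#' @export
invertTransform <- function(transform) {
  m <- transform@matrix
  R <- t(m[1:3, 1:3])
  inv <- diag(4)
  inv[1:3, 1:3] <- R
  inv[1:3, 4] <- -R %*% m[1:3, 4]
  new("RigidTransform", matrix = inv)
}

#' Compose two rigid transforms
#'
#' `composeTransforms(a, b)` applies `b` first, then `a`.
#'
#' @param a,b [RigidTransform-class] objects.
#' @return Their composition.
#' @export
composeTransforms <- function(a, b) {
  new("RigidTransform", matrix = a@matrix %*% b@matrix)
}

#' @describeIn RigidTransform-class Apply to an n x 3 matrix of mm points.
#' @param transform,points Transform and points.
#' @export
setMethod("applyTransform", signature("RigidTransform", "matrix"),
  function(transform, points) {
    m <- transform@matrix
    sweep(points %*% t(m[1:3, 1:3]), 2, m[1:3, 4], `+`)
  })

#' @export
setMethod("applyTransform", signature("RigidTransform", "numeric"),
  function(transform, points) {
    drop(applyTransform(transform, matrix(points, 1)))
  })

#' Geometric centre of a set of registration trials
#'
#' Component-wise arithmetic mean of the six pose parameters over all
#' trials; serves as the gold standard the individual trials are compared
#' against. Averaging is done in parameter space, which for the small
#' angular spreads at issue differs negligibly from rotation-group
#' averaging.
#'
#' @param trialSet A [TrialSet-class] (or plain list of
#'   [RigidParams-class]).
#' @return A [RigidParams-class].
#' @export
geometricCenter <- function(trialSet) {
  tl <- if (is(trialSet, "TrialSet")) trialSet@trials else trialSet
  if (length(tl) == 0) stop("need at least one trial")
  tr <- colMeans(do.call(rbind, lapply(tl, function(p) p@translation)))
  ro <- colMeans(do.call(rbind, lapply(tl, function(p) p@rotation)))
  RigidParams(tr[1], tr[2], tr[3], ro[1], ro[2], ro[3])
}

paramsToList <- function(p) {
  list(tx = p@translation[1], ty = p@translation[2], tz = p@translation[3],
       rx = p@rotation[1], ry = p@rotation[2], rz = p@rotation[3])
}

paramsFromList <- function(l) {
  RigidParams(l$tx, l$ty, l$tz, l$rx, l$ry, l$rz)
}

#' Read / write trial sets
#'
#' JSON layout: `{"label": str, "trials": [{"tx": .., "ty": .., "tz": ..,
#' "rx": .., "ry": .., "rz": ..}, ...]}`. CSV carries the same six columns
#' plus `label`.
#'
#' @param path File path (`.json` or `.csv`).
#' @return [readTrialSet()] returns a [TrialSet-class].
#' @export
readTrialSet <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- utils::read.csv(path)
    lab <- if ("label" %in% names(df)) as.character(df$label[1]) else "trials"
    tl <- lapply(seq_len(nrow(df)), function(i)
      RigidParams(df$tx[i], df$ty[i], df$tz[i], df$rx[i], df$ry[i], df$rz[i]))
    return(TrialSet(lab, tl))
  }
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  TrialSet(obj$label, lapply(obj$trials, paramsFromList))
}

#' @param trialSet A [TrialSet-class].
#' @rdname readTrialSet
#' @export
writeTrialSet <- function(trialSet, path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- do.call(rbind, lapply(trialSet@trials, function(p)
      as.data.frame(paramsToList(p))))
    df$label <- trialSet@label
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(label = trialSet@label,
           trials = lapply(trialSet@trials, paramsToList)),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
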