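# Simulated surgical photograph: projected vein marks with dropout,
# artery confounders, occlusions and a known misalignment, plus the
# closed-loop validation driver.

jitterPolyline <- function(p, sd) {
  if (sd <= 0) return(p)
  p + matrix(stats::rnorm(length(p), 0, sd), nrow(p), ncol(p))
}

polylineBBoxPolygon <- function(p, margin = 2) {
  lo <- apply(p, 2, min) - margin
  hi <- apply(p, 2, max) + margin
  rbind(c(lo[1], lo[2]), c(hi[1], lo[2]), c(hi[1], hi[2]), c(lo[1], hi[2]))
}

#' Generate a simulated annotated photograph from a phantom
#'
#' Projects the vein tree into the view and builds, with vertex jitter,
#' the reconstruction mark set and the photo mark set: a dropout fraction
#' of veins is absent from the photo (ground-truth Category 2 for their
#' reconstruction marks), extra photo-only traces appear (Category 1),
#' some reconstruction sections face an artery trace instead of a vein
#' (Category 3), and some are covered by an occlusion polygon
#' (Category 4); the rest correspond (Category 0). All photo-side
#' geometry — sections, occlusions, landmarks — is mapped through the
#' configured misalignment similarity. The alignment landmarks model
#' cortical landmarks visible in both media: the true projected polyline
#' endpoints with independent per-side jitter, so the photograph stays
#' alignable whatever the vein confounders remove.
#'
#' @param phantom A [Phantom-class].
#' @param view A [StandardView-class] (default the cranial view).
#' @param config The [PhantomConfig-class] (confounder rates, jitter,
#'   misalignment).
#' @param seed Integer seed.
#' @return List with `reconMarks` and `photoMarks`
#'   ([VeinMarkSet-class]), `reconLandmarks`/`photoLandmarks` (matched
#'   n x 2 point sets), `truth` (data.frame: `kind`, `index`,
#'   `category`), `photoImage` (grayscale matrix), `misalignment`.
#' @export
generatePhoto <- function(phantom, view = standardView(1),
                          config = phantomConfig(), seed) {
  withr::with_seed(seed, {
    polys <- projectPolylines(phantom@tree, view)
    veinIds <- names(polys)
    n <- length(polys)
    if (n < 3) stop("phantom has too few veins for a photo simulation")

    reconSections <- lapply(polys, jitterPolyline, sd = config@jitterSD)
    reconMarks <- VeinMarkSet("reconstruction", unname(reconSections))

    idx <- seq_len(n)
    nConf <- min(config@arteryCount + config@occlusionCount, n - 2L)
    conf <- if (nConf > 0) sample(idx, nConf) else integer()
    arteryIdx <- utils::head(conf, config@arteryCount)
    occlIdx <- utils::tail(conf, nConf - length(arteryIdx))
    rest <- setdiff(idx, conf)
    dropIdx <- rest[stats::runif(length(rest)) < config@photoDropout]
    cat0Idx <- setdiff(rest, dropIdx)

    truthRecon <- integer(n)
    truthRecon[dropIdx] <- 2L
    truthRecon[arteryIdx] <- 3L
    truthRecon[occlIdx] <- 4L

    mis <- config@misalignment
    photoSections <- list()
    photoKinds <- character()
    photoOf <- rep(NA_integer_, n)  # photo index of each vein, if present
    for (i in idx) {
      if (truthRecon[i] %in% c(0L, 3L)) {
        sec <- applySimilarity(mis, jitterPolyline(polys[[i]],
                                                   config@jitterSD))
        photoSections[[length(photoSections) + 1L]] <- sec
        photoKinds <- c(photoKinds,
                        if (truthRecon[i] == 3L) "artery" else "vein")
        photoOf[i] <- length(photoSections)
      }
    }
    occlusions <- lapply(occlIdx, function(i)
      applySimilarity(mis, polylineBBoxPolygon(reconSections[[i]])))

    nExtra <- stats::rpois(1, config@photoExtraRate)
    extraIdx <- integer()
    if (nExtra > 0) {
      allPts <- do.call(rbind, reconSections)
      u1 <- max(allPts[, 1]) + 15
      vmid <- mean(range(allPts[, 2]))
      for (k in seq_len(nExtra)) {
        u <- u1 + (k - 1) * 10
        extra <- cbind(c(u, u + 2, u + 3), c(vmid - 8, vmid, vmid + 8))
        photoSections[[length(photoSections) + 1L]] <-
          applySimilarity(mis, extra)
        photoKinds <- c(photoKinds, "vein")
        extraIdx <- c(extraIdx, length(photoSections))
      }
    }
    photoMarks <- VeinMarkSet("photo", photoSections, photoKinds, occlusions)

    # Alignment landmarks model cortical landmarks visible in both media,
    # independent of which veins survive in the photo: the true projected
    # polyline endpoints, with independent per-side jitter.
    lmTrue <- do.call(rbind, lapply(polys, function(s)
      s[c(1, nrow(s)), , drop = FALSE]))
    lmRecon <- jitterPolyline(lmTrue, config@jitterSD)
    lmPhoto <- applySimilarity(mis, jitterPolyline(lmTrue, config@jitterSD))

    truth <- rbind(
      data.frame(kind = "recon", index = idx, veinId = veinIds,
                 category = truthRecon),
      if (length(extraIdx))
        data.frame(kind = "photo", index = extraIdx, veinId = NA,
                   category = 1L))

    list(reconMarks = reconMarks, photoMarks = photoMarks,
         reconLandmarks = lmRecon, photoLandmarks = lmPhoto,
         truth = truth, misalignment = mis,
         photoImage = renderPhotoImage(photoSections, photoKinds))
  })
}

# Simple grayscale rendering of the photo marks: bright cortex, dark
# veins, mid-gray arteries.
renderPhotoImage <- function(sections, kinds, pixelSize = 1) {
  if (!length(sections)) return(matrix(0.9, 8, 8))
  allPts <- do.call(rbind, sections)
  lo <- apply(allPts, 2, min) - 5
  hi <- apply(allPts, 2, max) + 5
  ni <- ceiling((hi[1] - lo[1]) / pixelSize)
  nj <- ceiling((hi[2] - lo[2]) / pixelSize)
  img <- matrix(0.9, ni, nj)
  for (k in seq_along(sections)) {
    p <- resamplePolyline(sections[[k]], pixelSize / 2)
    i <- pmin(ni, pmax(1, floor((p[, 1] - lo[1]) / pixelSize) + 1))
    j <- pmin(nj, pmax(1, floor((p[, 2] - lo[2]) / pixelSize) + 1))
    img[cbind(i, j)] <- if (kinds[k] == "artery") 0.5 else 0.2
  }
  img
}

#' Run the closed-loop photo validation
#'
#' Aligns the photo marks to the reconstruction frame with the
#' least-squares similarity fitted on the matched landmarks, classifies
#' every section and summarizes the categories.
#'
#' @param bundle Output of [generatePhoto()].
#' @param tol Match tolerance in mm.
#' @return List with `fit` ([Similarity2D-class]), `classification`
#'   (data.frame from [classifySections()]) and `summary`
#'   ([CategorySummary-class]).
#' @export
runValidation <- function(bundle, tol = 3) {
  fit <- fitSimilarity(bundle$photoLandmarks, bundle$reconLandmarks)
  pm <- bundle$photoMarks
  aligned <- VeinMarkSet("photo",
                         applySimilarity(fit, pm@sections),
                         pm@kind,
                         applySimilarity(fit, pm@occlusions))
  classification <- classifySections(bundle$reconMarks, aligned, tol = tol)
  list(fit = fit, classification = classification,
       summary = summarizeCategories(classification))
}

#' Fraction of sections recovering their ground-truth category
#'
#' @param bundle Output of [generatePhoto()].
#' @param classification data.frame from [classifySections()] /
#'   [runValidation()].
#' @return Fraction in `[0, 1]` of truth sections (reconstruction marks
#'   plus photo-only traces) assigned their ground-truth category.
#' @export
categoryRecovery <- function(bundle, classification) {
  truth <- bundle$truth
  ok <- 0L
  for (k in seq_len(nrow(truth))) {
    if (truth$kind[k] == "recon") {
      i <- truth$index[k]
      inPair <- any(classification$source == "pair" &
                    classification$reconIndex == i)
      assigned <- if (inPair) 0L else {
        row <- classification$source == "recon" &
               classification$reconIndex == i
        if (any(row)) classification$category[row][1] else NA_integer_
      }
    } else {
      j <- truth$index[k]
      assigned <- if (any(classification$source == "photo" &
                          classification$photoIndex == j)) 1L else 0L
    }
    if (!is.na(assigned) && assigned == truth$category[k]) ok <- ok + 1L
  }
  ok / nrow(truth)
}

#' Write a photo bundle to disk
#'
#' The simulated photograph as PNG, both mark sets as JSON, and the truth
#' table as CSV.
#'
#' @param bundle Output of [generatePhoto()].
#' @param dir Output directory.
#' @export
writePhotoBundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  img <- bundle$photoImage
  png::writePNG(t(img)[rev(seq_len(ncol(img))), , drop = FALSE],
                file.path(dir, "photo.png"))
  writeVeinMarkSet(bundle$reconMarks, file.path(dir, "recon_marks.json"))
  writeVeinMarkSet(bundle$photoMarks, file.path(dir, "photo_marks.json"))
  utils::write.csv(bundle$truth, file.path(dir, "truth_categories.csv"),
                   row.names = FALSE)
  invisible(dir)
}
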