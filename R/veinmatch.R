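# Five-category validation of the vein reconstruction against the
# annotated photograph: section matching, classification, frequencies.

#' @describeIn VeinMarkSet-class The list of section polylines.
#' @param x Object.
#' @export
setMethod("sections", "VeinMarkSet", function(x) x@sections)

setMethod("show", "VeinMarkSet", function(object) {
  cat(sprintf("VeinMarkSet [%s]: %d sections (%d veins, %d arteries), %d occlusion polygons\n",
              object@source, length(object@sections),
              sum(object@kind == "vein"), sum(object@kind == "artery"),
              length(object@occlusions)))
})

#' Classify marked vein sections into the five validation categories
#'
#' Reconstruction vein sections are matched one-to-one to photo vein
#' sections greedily in ascending order of mean symmetric polyline
#' distance (ties broken by lower section index); only pairs at distance
#' <= `tol` match. Each matched pair is one Category 0 section. Unmatched
#' photo veins are Category 1 (visible in the photo, missing from the
#' reconstruction). Unmatched reconstruction sections are Category 3 if
#' some photo artery trace lies within `tol`, Category 4 if at least half
#' of their arc length falls inside an occlusion polygon, and Category 2
#' otherwise.
#'
#' Both mark sets must already be in the common aligned frame (see
#' [fitSimilarity()]).
#'
#' @param recon Reconstruction [VeinMarkSet-class] (veins only).
#' @param photo Photo [VeinMarkSet-class] (veins, arteries, occlusions).
#' @param tol Match tolerance in mm (> 0).
#' @param step Polyline resampling step in mm.
#' @return data.frame with one row per categorized section: columns
#'   `category` (0-4), `source` (`"pair"`, `"photo"`, `"recon"`),
#'   `reconIndex`, `photoIndex` (NA where not applicable).
#' @export
classifySections <- function(recon, photo, tol = 3, step = 0.5) {
  if (tol <= 0) stop("tol must be positive")
  rv <- which(recon@kind == "vein")
  pv <- which(photo@kind == "vein")
  pa <- which(photo@kind == "artery")

  # Pairwise scores between recon veins and photo veins.
  pairs <- NULL
  if (length(rv) && length(pv)) {
    d <- matrix(Inf, length(rv), length(pv))
    for (i in seq_along(rv)) {
      for (j in seq_along(pv)) {
        d[i, j] <- meanSymmetricDistance(recon@sections[[rv[i]]],
                                         photo@sections[[pv[j]]], step)
      }
    }
    cand <- which(d <= tol, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(d[cand], cand[, 1], cand[, 2])
      cand <- cand[ord, , drop = FALSE]
      usedR <- logical(length(rv)); usedP <- logical(length(pv))
      for (k in seq_len(nrow(cand))) {
        i <- cand[k, 1]; j <- cand[k, 2]
        if (!usedR[i] && !usedP[j]) {
          usedR[i] <- TRUE; usedP[j] <- TRUE
          pairs <- rbind(pairs, c(rv[i], pv[j]))
        }
      }
    }
  }

  matchedR <- if (is.null(pairs)) integer() else pairs[, 1]
  matchedP <- if (is.null(pairs)) integer() else pairs[, 2]
  rows <- list()
  if (!is.null(pairs)) {
    rows[[length(rows) + 1L]] <- data.frame(
      category = 0L, source = "pair",
      reconIndex = pairs[, 1], photoIndex = pairs[, 2])
  }
  unmatchedP <- setdiff(pv, matchedP)
  if (length(unmatchedP)) {
    rows[[length(rows) + 1L]] <- data.frame(
      category = 1L, source = "photo",
      reconIndex = NA_integer_, photoIndex = unmatchedP)
  }
  for (i in setdiff(rv, matchedR)) {
    sec <- recon@sections[[i]]
    cat_i <- 2L
    if (length(pa)) {
      da <- vapply(pa, function(j)
        meanSymmetricDistance(sec, photo@sections[[j]], step), numeric(1))
      if (any(da <= tol)) cat_i <- 3L
    }
    if (cat_i == 2L && length(photo@occlusions)) {
      if (occludedFraction(sec, photo@occlusions, step) >= 0.5) cat_i <- 4L
    }
    rows[[length(rows) + 1L]] <- data.frame(
      category = cat_i, source = "recon",
      reconIndex = i, photoIndex = NA_integer_)
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(category = integer(), source = character(),
                      reconIndex = integer(), photoIndex = integer())
  rownames(out) <- NULL
  out
}

# Fraction of a polyline's resampled arc inside any of the polygons.
occludedFraction <- function(section, polygons, step = 0.5) {
  p <- resamplePolyline(section, step)
  inside <- rep(FALSE, nrow(p))
  for (poly in polygons) {
    inside <- inside | pracma::inpolygon(p[, 1], p[, 2],
                                         poly[, 1], poly[, 2],
                                         boundary = TRUE)
  }
  mean(inside)
}

#' Summarize section categories
#'
#' Counts per category with one-decimal percentages of the total, plus the
#' derived totals: photo-visible veins (categories 0 + 1) and
#' reconstruction-visible sections (categories 0 + 2 + 3 + 4).
#'
#' @param categories Integer vector of categories 0-4 (or the data.frame
#'   from [classifySections()]).
#' @return A [CategorySummary-class].
#' @export
summarizeCategories <- function(categories) {
  if (is.data.frame(categories)) categories <- categories$category
  if (length(categories) == 0) stop("no categorized sections")
  if (any(!categories %in% 0:4)) stop("categories must be in 0..4")
  counts <- vapply(0:4, function(k) sum(categories == k), integer(1))
  new("CategorySummary", counts = counts)
}

#' @describeIn CategorySummary-class Named counts n0..n4 plus totals:
#'   `total`, `photo_visible` (n0+n1), `recon_visible` (n0+n2+n3+n4).
#' @param x Object.
#' @export
setMethod("categoryCounts", "CategorySummary", function(x) {
  n <- x@counts
  c(n0 = n[1], n1 = n[2], n2 = n[3], n3 = n[4], n4 = n[5],
    total = sum(n), photo_visible = n[1] + n[2],
    recon_visible = n[1] + n[3] + n[4] + n[5])
})

#' @describeIn CategorySummary-class Percentages of the total, rounded to
#'   one decimal.
#' @export
setMethod("categoryPercentages", "CategorySummary", function(x) {
  n <- x@counts
  p <- round(100 * n / sum(n), 1)
  names(p) <- paste0("pct", 0:4)
  p
})

setMethod("show", "CategorySummary", function(object) {
  cc <- categoryCounts(object)
  pp <- categoryPercentages(object)
  cat("CategorySummary:\n")
  for (k in 0:4) {
    cat(sprintf("  Category %d: %3d (%5.1f%%)\n", k, cc[[k + 1]], pp[[k + 1]]))
  }
  cat(sprintf("  total %d | photo-visible %d | reconstruction-visible %d\n",
              cc[["total"]], cc[["photo_visible"]], cc[["recon_visible"]]))
})

#' Serialize a category summary
#'
#' @param x A [CategorySummary-class].
#' @param path Output path (`.json` or `.csv`).
#' @export
writeCategorySummary <- function(x, path) {
  cc <- categoryCounts(x)
  pp <- categoryPercentages(x)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) {
    df <- data.frame(category = 0:4, count = as.integer(cc[1:5]),
                     percent = as.numeric(pp))
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(c(as.list(cc), as.list(pp)), path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' Read / write vein mark sets as JSON
#'
#' Layout: `{"source": str, "sections": [{"kind": str, "points":
#' [[u,v],...]}, ...], "occlusions": [[[u,v],...], ...]}` with mm
#' coordinates.
#'
#' @param path File path.
#' @return [readVeinMarkSet()] returns a [VeinMarkSet-class].
#' @export
readVeinMarkSet <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  secs <- lapply(obj$sections, function(s)
    do.call(rbind, lapply(s$points, unlist)))
  kinds <- vapply(obj$sections, function(s) s$kind, character(1))
  occl <- lapply(obj$occlusions, function(p) do.call(rbind, lapply(p, unlist)))
  VeinMarkSet(obj$source, secs, kinds, occl)
}

#' @param marks A [VeinMarkSet-class].
#' @rdname readVeinMarkSet
#' @export
writeVeinMarkSet <- function(marks, path) {
  obj <- list(
    source = marks@source,
    sections = lapply(seq_along(marks@sections), function(i)
      list(kind = marks@kind[i],
           points = unname(apply(marks@sections[[i]], 1, as.list,
                                 simplify = FALSE)))),
    occlusions = lapply(marks@occlusions, function(p)
      unname(apply(p, 1, as.list, simplify = FALSE))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
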