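# Five-metric evaluation protocol with physical-unit surface distances,
# explicit empty-mask conventions, lesion axial-diameter stratification and
# mean/median aggregation.
#
# Conventions (the literature names the metrics but not the discretisation;
# these are the dominant community choices, applied consistently):
#  * a surface voxel is a mask voxel with at least one background
#    6-neighbour, out-of-grid counting as background;
#  * distances are Euclidean between voxel centres, in mm;
#  * both masks empty: Dice = 1, distances = 0 (perfect agreement);
#    exactly one empty: distances = +Inf, recall = precision = 0.

checkGrids <- function(a, b) {
  if (!identical(dim(a), dim(b)))
    stop("masks must share one grid shape")
}

asMaskArray <- function(m) {
  if (is(m, "ImageVolume")) m@values else m
}

#' Dice overlap between two binary masks
#'
#' \code{2|GT n PR| / (|GT| + |PR|)}; both masks empty gives 1 by
#' convention.
#'
#' @param gt,pr binary arrays (or mask \linkS4class{ImageVolume}s) on one
#'   grid
#' @return fraction in [0, 1]
#' @export
diceScore <- function(gt, pr) {
  gt <- asMaskArray(gt); pr <- asMaskArray(pr)
  checkGrids(gt, pr)
  sg <- sum(gt); sp <- sum(pr)
  if (sg + sp == 0) return(1)
  2 * sum(gt * pr) / (sg + sp)
}

#' Voxelwise recall (sensitivity)
#'
#' \code{TP / (TP + FN)}; an empty ground truth gives 0 by decision.
#' @inheritParams diceScore
#' @export
recallScore <- function(gt, pr) {
  gt <- asMaskArray(gt); pr <- asMaskArray(pr)
  checkGrids(gt, pr)
  sg <- sum(gt)
  if (sg == 0) return(0)
  sum(gt * pr) / sg
}

#' Voxelwise precision (positive predictive value)
#'
#' \code{TP / (TP + FP)}; an empty prediction gives 0 by decision.
#' @inheritParams diceScore
#' @export
precisionScore <- function(gt, pr) {
  gt <- asMaskArray(gt); pr <- asMaskArray(pr)
  checkGrids(gt, pr)
  sp <- sum(pr)
  if (sp == 0) return(0)
  sum(gt * pr) / sp
}

surfaceMask <- function(m) {
  d <- dim(m)
  pad <- array(0, d + 2L)
  pad[2:(d[1] + 1), 2:(d[2] + 1), 2:(d[3] + 1)] <- m
  nb <- pad[1:d[1], 2:(d[2] + 1), 2:(d[3] + 1)] *
        pad[3:(d[1] + 2), 2:(d[2] + 1), 2:(d[3] + 1)] *
        pad[2:(d[1] + 1), 1:d[2], 2:(d[3] + 1)] *
        pad[2:(d[1] + 1), 3:(d[2] + 2), 2:(d[3] + 1)] *
        pad[2:(d[1] + 1), 2:(d[2] + 1), 1:d[3]] *
        pad[2:(d[1] + 1), 2:(d[2] + 1), 3:(d[3] + 2)]
  m * (nb == 0) # mask voxel with at least one background 6-neighbour
}

#' Surface voxel centres in millimetres
#'
#' Returns the physical centres of the mask voxels that have at least one
#' background 6-neighbour (out-of-grid counts as background).
#'
#' @param mask binary array or mask \linkS4class{ImageVolume}
#' @param spacing numeric (z, y, x) mm; taken from the volume when omitted
#' @return numeric matrix with columns (z, y, x) in mm, one row per surface
#'   voxel (0 rows for an empty mask)
#' @export
surfaceVoxels <- function(mask, spacing = NULL) {
  if (is(mask, "ImageVolume")) {
    if (is.null(spacing)) spacing <- mask@spacing
    mask <- mask@values
  }
  s <- surfaceMask(mask)
  idx <- which(s != 0, arr.ind = TRUE)
  pts <- sweep(idx - 1, 2, spacing, `*`)
  colnames(pts) <- c("z", "y", "x")
  pts
}

# directed surface distances via the exact Euclidean distance transform of
# the opposing surface; exact because surface voxel centres lie on the grid
surfaceDistances <- function(sa, sb, spacing) {
  edt <- sqrt(cpp_edt_sq(array(as.integer(sb != 0), dim(sb)),
                         as.numeric(spacing)))
  edt[sa != 0]
}

#' Hausdorff distance between two masks, in mm
#'
#' The exact (100th percentile) symmetric Hausdorff distance between the
#' mask surfaces: the worst-case nearest-surface distance over both
#' directions. One empty mask gives \code{+Inf}; two empty masks give 0.
#'
#' @inheritParams diceScore
#' @param spacing numeric (z, y, x) mm; taken from the volumes when omitted
#' @export
hausdorffMM <- function(gt, pr, spacing = NULL) {
  if (is.null(spacing) && is(gt, "ImageVolume")) spacing <- gt@spacing
  gt <- asMaskArray(gt); pr <- asMaskArray(pr)
  checkGrids(gt, pr)
  eg <- sum(gt) == 0; ep <- sum(pr) == 0
  if (eg && ep) return(0)
  if (eg || ep) return(Inf)
  sg <- surfaceMask(gt); sp <- surfaceMask(pr)
  max(surfaceDistances(sg, sp, spacing), surfaceDistances(sp, sg, spacing))
}

#' Average symmetric surface distance, in mm
#'
#' Mean over both surfaces of each surface point's distance to the nearest
#' point of the other surface. Empty-mask conventions as
#' \code{\link{hausdorffMM}}.
#'
#' @inheritParams hausdorffMM
#' @export
asdMM <- function(gt, pr, spacing = NULL) {
  if (is.null(spacing) && is(gt, "ImageVolume")) spacing <- gt@spacing
  gt <- asMaskArray(gt); pr <- asMaskArray(pr)
  checkGrids(gt, pr)
  eg <- sum(gt) == 0; ep <- sum(pr) == 0
  if (eg && ep) return(0)
  if (eg || ep) return(Inf)
  sg <- surfaceMask(gt); sp <- surfaceMask(pr)
  d1 <- surfaceDistances(sg, sp, spacing)
  d2 <- surfaceDistances(sp, sg, spacing)
  (sum(d1) + sum(d2)) / (length(d1) + length(d2))
}

# max pairwise distance among 2D points (mm); convex hull first when the
# point set is large
maxPairwise2d <- function(pts) {
  if (nrow(pts) < 2) return(0)
  if (nrow(pts) > 8) {
    h <- grDevices::chull(pts)
    pts <- pts[h, , drop = FALSE]
  }
  dm <- stats::dist(pts)
  max(dm)
}

#' Lesion axial diameter, in mm
#'
#' Per 26-connected component, the maximum over axial (constant-depth)
#' slices of the largest in-plane Euclidean distance between voxel centres
#' (a Feret-style diameter); the case value is the maximum over components.
#' An empty mask returns 0.
#'
#' @param mask binary lesion array or mask \linkS4class{ImageVolume}
#' @param spacing numeric (z, y, x) mm; taken from the volume when omitted
#' @export
lesionAxialDiameter <- function(mask, spacing = NULL) {
  if (is(mask, "ImageVolume")) {
    if (is.null(spacing)) spacing <- mask@spacing
    mask <- mask@values
  }
  if (sum(mask) == 0) return(0)
  lab <- cpp_label_components(array(as.integer(mask != 0), dim(mask)))
  idx <- which(lab != 0, arr.ind = TRUE)
  comp <- lab[lab != 0]
  best <- 0
  for (cc in unique(comp)) {
    sub <- idx[comp == cc, , drop = FALSE]
    for (z in unique(sub[, 1])) {
      pl <- sub[sub[, 1] == z, 2:3, drop = FALSE]
      pts <- sweep(pl - 1, 2, spacing[2:3], `*`)
      best <- max(best, maxPairwise2d(pts))
    }
  }
  best
}

#' Assign a diameter to a lesion-size stratum
#'
#' \code{d < 15} is "0-15"; \code{15 <= d <= 30} is "15-30" (a lesion at
#' exactly 15 mm belongs to the intermediate group, matching the
#' non-overlapping table ranges and the "less than 15 mm" definition of
#' small lesions); \code{d > 30} is ">30".
#'
#' @param diameterMM numeric, non-negative
#' @return character stratum label
#' @export
stratifyDiameter <- function(diameterMM) {
  if (any(diameterMM < 0)) stop("diameter must be non-negative")
  ifelse(diameterMM < 15, "0-15", ifelse(diameterMM <= 30, "15-30", ">30"))
}

#' Per-case metric vector
#'
#' Computes the five metrics plus the ground-truth lesion axial diameter
#' and its stratum for one case.
#'
#' @param gt,pr binary masks (arrays or \linkS4class{ImageVolume}s)
#' @param spacing numeric (z, y, x) mm
#' @param id case identifier
#' @return one-row data.frame: id, dice, hausdorff_mm, asd_mm, recall,
#'   precision, lesion_diameter_mm, stratum
#' @export
caseMetrics <- function(gt, pr, spacing = NULL, id = "case") {
  if (is.null(spacing) && is(gt, "ImageVolume")) spacing <- gt@spacing
  d <- lesionAxialDiameter(gt, spacing)
  data.frame(id = id,
             dice = diceScore(gt, pr),
             hausdorff_mm = hausdorffMM(gt, pr, spacing),
             asd_mm = asdMM(gt, pr, spacing),
             recall = recallScore(gt, pr),
             precision = precisionScore(gt, pr),
             lesion_diameter_mm = d,
             stratum = stratifyDiameter(d),
             stringsAsFactors = FALSE)
}

#' Aggregate per-case metrics into a stratified report
#'
#' Means for Dice, recall and precision; medians for the distance metrics
#' (for an even count, the mean of the central pair; \code{+Inf} sentinels
#' from empty predictions participate in the ordering, which is exactly why
#' the median is reported for distances). Computed overall and per
#' lesion-size stratum.
#'
#' @param cases data.frame as returned by \code{\link{caseMetrics}} (one
#'   row per case)
#' @return data.frame with one row per stratum present plus "overall":
#'   stratum, n, dice_mean, recall_mean, precision_mean, hausdorff_median,
#'   asd_median
#' @export
aggregateMetrics <- function(cases) {
  if (!is.data.frame(cases) || nrow(cases) == 0)
    stop("need a nonempty data.frame of per-case metrics")
  onegroup <- function(df, label) {
    data.frame(stratum = label, n = nrow(df),
               dice_mean = mean(df$dice),
               recall_mean = mean(df$recall),
               precision_mean = mean(df$precision),
               hausdorff_median = stats::median(df$hausdorff_mm),
               asd_median = stats::median(df$asd_mm),
               stringsAsFactors = FALSE)
  }
  strata <- intersect(c(strataNames()), unique(cases$stratum))
  out <- do.call(rbind, c(
    lapply(strata, function(s) onegroup(cases[cases$stratum == s, ], s)),
    list(onegroup(cases, "overall"))))
  rownames(out) <- NULL
  out
}
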