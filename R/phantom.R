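# Synthetic phantom cases: ellipsoidal gland + ellipsoidal lesions on a
# three-channel grid with native anisotropic spacing. Every downstream stage
# (preprocessing, training, metrics) is testable against these without any
# external imaging data.

# Lesion semiaxes (z, y, x) in mm for a requested axial diameter: the axial
# (in-plane) diameter is controlled by the two in-plane semiaxes; the
# through-plane semiaxis defaults to half the in-plane radius, capped by
# half the gland z-semiaxis so the lesion can be placed off-centre.
lesionSemiaxes <- function(diameter_mm, glandSemiaxes) {
  r <- diameter_mm / 2
  c(min(r / 2, glandSemiaxes[1] / 2), r, r)
}

# evaluate with a local, restorable RNG state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

# rasterise an axis-aligned ellipsoid by voxel-centre inclusion:
# a voxel belongs iff its centre lies inside the analytic ellipsoid
ellipsoidMask <- function(gridShape, spacing, center_mm, semiaxes_mm) {
  z <- ((seq_len(gridShape[1]) - 1) * spacing[1] - center_mm[1]) / semiaxes_mm[1]
  y <- ((seq_len(gridShape[2]) - 1) * spacing[2] - center_mm[2]) / semiaxes_mm[2]
  x <- ((seq_len(gridShape[3]) - 1) * spacing[3] - center_mm[3]) / semiaxes_mm[3]
  q <- outer(outer(z^2, y^2, `+`), x^2, `+`)
  array(as.numeric(q <= 1), gridShape)
}

#' Generate one synthetic phantom case
#'
#' Builds a three-channel prostate-like case from a \linkS4class{PhantomSpec}:
#' an ellipsoidal whole gland centred in the grid, one ellipsoid per
#' requested lesion diameter placed uniformly at random (in gland-normalised
#' coordinates) so that each lesion lies entirely inside the gland and
#' lesions do not touch, piecewise-constant channel intensities
#' (background / gland / lesion) and optional additive Gaussian noise.
#' The case is fully determined by the spec and its seed.
#'
#' @param spec a \linkS4class{PhantomSpec}
#' @return a \linkS4class{ProstateCase}
#' @examples
#' case <- generateCase(PhantomSpec(lesionDiametersMM = 12, seed = 7))
#' case
#' @export
generateCase <- function(spec) {
  validObject(spec)
  gs <- spec@gridShape
  sp <- spec@spacingMM
  A <- spec@glandSemiaxesMM
  center <- (gs - 1) * sp / 2
  withSeed(spec@seed, {
    gland <- ellipsoidMask(gs, sp, center, A)
    lesion <- array(0, gs)
    placed <- list()
    for (d in spec@lesionDiametersMM) {
      ax <- lesionSemiaxes(d, A)
      m <- max(ax / A)
      if (m >= 1)
        stop(sprintf("lesion with diameter %.6g mm cannot fit inside the gland", d))
      # sample a centre inside the ball of radius (1 - m) in gland-normalised
      # coordinates: the lesion ellipsoid then lies inside the unit ball
      ok <- FALSE
      for (try in seq_len(200L)) {
        u <- stats::rnorm(3)
        u <- u / sqrt(sum(u^2))
        rad <- (1 - m) * 0.95 * stats::runif(1)^(1 / 3)
        cen <- center + u * rad * A
        # snap the centre onto an axial grid plane so the widest in-plane
        # cross-section is actually sampled (the slice pitch is coarse)
        cen[1] <- round(cen[1] / sp[1]) * sp[1]
        if (sqrt(sum(((cen - center) / A)^2)) + m >= 0.999) next
        clear <- all(vapply(placed, function(p) {
          sqrt(sum((cen - p$cen)^2)) > max(ax) + max(p$ax) + 2 * max(sp)
        }, logical(1)))
        if (clear) { ok <- TRUE; break }
      }
      if (!ok)
        stop(sprintf("could not place lesion of diameter %.6g mm without overlap", d))
      placed <- c(placed, list(list(cen = cen, ax = ax)))
      lesion <- pmax(lesion, ellipsoidMask(gs, sp, cen, ax))
    }
    gland <- pmax(gland, lesion) # numerical safety at the rim
    chans <- vector("list", 3)
    for (ch in 1:3) {
      co <- spec@contrast[ch, ]
      v <- array(co[1], gs)
      v[gland == 1] <- co[2]
      v[lesion == 1] <- co[3]
      if (spec@noiseSigma > 0) {
        sd_ch <- spec@noiseSigma * abs(co[2] - co[3])
        v <- v + array(stats::rnorm(prod(gs), sd = sd_ch), gs)
      }
      chans[[ch]] <- ImageVolume(v, sp)
    }
    ProstateCase(id = sprintf("phantom-%06d", spec@seed),
                 t2w = chans[[1]], adc = chans[[2]], dwi = chans[[3]],
                 wgMask = ImageVolume(gland, sp, mask = TRUE),
                 lesionMask = ImageVolume(lesion, sp, mask = TRUE))
  })
}

# Largest-remainder apportionment of n cases over strata proportions.
# Quotas q = n * p are floored; the remaining cases go to the strata with
# the largest fractional remainders, ties broken in stratum order
# (0-15 first, then 15-30, then >30).
apportionStrata <- function(n, mix) {
  if (abs(sum(mix) - 1) > 1e-9)
    stop("strata proportions must sum to 1 (within 1e-9)")
  q <- n * mix
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    ord <- order(-(q - base), seq_along(mix))
    base[ord[seq_len(rem)]] <- base[ord[seq_len(rem)]] + 1
  }
  as.integer(base)
}

strataNames <- function() c("0-15", "15-30", ">30")

# diameter sampling ranges per stratum (mm); kept inside what the default
# gland can host
strataDiameterRange <- function(stratum) {
  switch(stratum,
         "0-15" = c(6, 14.5),
         "15-30" = c(15, 29),
         ">30" = c(30.5, 36))
}

#' Plan a synthetic cohort
#'
#' Apportions \code{n} cases over the three lesion-size strata
#' (0-15 / 15-30 / >30 mm axial diameter) by the largest-remainder rule,
#' samples one requested diameter per case uniformly within its stratum
#' range, and returns one \linkS4class{PhantomSpec} per case together with
#' the manifest. Use this instead of \code{\link{generateCohort}} to stream
#' large cohorts case by case.
#'
#' @param n number of cases
#' @param mix length-3 proportions over the strata, summing to 1; the
#'   default mirrors an external-validation distribution of 61.5\% small,
#'   34\% intermediate and 4.5\% large lesions
#' @param seed integer; case i uses seed \code{seed + i}
#' @param gridShape,spacingMM,glandSemiaxesMM,noiseSigma forwarded to
#'   \linkS4class{PhantomSpec}
#' @return list with \code{specs} (list of \linkS4class{PhantomSpec}) and
#'   \code{manifest} (data.frame: id, diameter_mm, stratum, seed)
#' @export
cohortSpecs <- function(n, mix = c(0.615, 0.34, 0.045), seed = 1L,
                        gridShape = c(20L, 160L, 160L), spacingMM = c(3, 1, 1),
                        glandSemiaxesMM = c(18, 24, 26), noiseSigma = 0.05) {
  stopifnot(n >= 1)
  counts <- apportionStrata(n, mix)
  strata <- rep(strataNames(), counts)
  diam <- withSeed(seed, {
    vapply(strata, function(s) {
      r <- strataDiameterRange(s)
      stats::runif(1, r[1], r[2])
    }, numeric(1))
  })
  ids <- sprintf("phantom-%06d", seed + seq_len(n))
  specs <- lapply(seq_len(n), function(i)
    PhantomSpec(gridShape = gridShape, spacingMM = spacingMM,
                glandSemiaxesMM = glandSemiaxesMM,
                lesionDiametersMM = diam[i], noiseSigma = noiseSigma,
                seed = seed + i))
  manifest <- data.frame(id = ids, diameter_mm = diam, stratum = strata,
                         seed = seed + seq_len(n), stringsAsFactors = FALSE)
  rownames(manifest) <- NULL
  list(specs = specs, manifest = manifest)
}

#' Generate a synthetic cohort
#'
#' Materialises the cohort planned by \code{\link{cohortSpecs}}. With
#' \code{outDir} set, each case is written as five NIfTI volumes plus a
#' manifest CSV and only the manifest is returned; otherwise all cases are
#' kept in memory (appropriate for small \code{n}).
#'
#' @inheritParams cohortSpecs
#' @param outDir optional output directory for NIfTI + manifest.csv
#' @param ... forwarded to \code{\link{cohortSpecs}}
#' @return list with \code{cases} (NULL when written to disk) and
#'   \code{manifest}
#' @export
generateCohort <- function(n, mix = c(0.615, 0.34, 0.045), seed = 1L,
                           outDir = NULL, ...) {
  plan <- cohortSpecs(n, mix, seed, ...)
  if (is.null(outDir)) {
    cases <- lapply(plan$specs, generateCase)
    return(list(cases = cases, manifest = plan$manifest))
  }
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(plan$specs)) {
    cs <- generateCase(plan$specs[[i]])
    writeCase(cs, outDir)
  }
  utils::write.csv(plan$manifest, file.path(outDir, "manifest.csv"),
                   row.names = FALSE)
  list(cases = NULL, manifest = plan$manifest)
}
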