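## Synthetic nerve cross-section generator. Emulates the reported structure
## of human cervical vagus fascicles — lognormal-mixture fiber calibers
## (small-fiber mode near 2 um, large-fiber mode near 9.5 um), truncated
## normal G-ratios, endoneurium/fascicle area ratios near 0.76-0.81,
## sub-fascicles in a configurable fraction of fascicles, right-dominant
## fascicle counts — so every other module is testable without any imaging
## data. Every drawn value is recorded in a ground-truth ledger so oracle
## tests never re-derive truth from outputs.

#' Fiber population specification
#'
#' @param nMyelinated,nUnmyelinated fiber counts (>= 0).
#' @param myelinatedMix data.frame (weight, meanlog, sdlog) of the lognormal
#'   diameter mixture in micrometres; the default is bimodal with modes near
#'   2 and 9.5 um.
#' @param unmyelinatedMix likewise; default unimodal near 1 um.
#' @param gRatioMean,gRatioSd truncated-normal G-ratio parameters.
#' @param gRatioRange truncation interval, default (0.4, 0.9).
#' @param seed RNG seed used by [samplePopulation()].
#' @return A list of class `PopulationSpec`.
#' @export
populationSpec <- function(nMyelinated = 100L, nUnmyelinated = 300L,
                           myelinatedMix = data.frame(
                             weight = c(0.7, 0.3),
                             meanlog = log(c(2.0, 9.5)),
                             sdlog = c(0.12, 0.08)),
                           unmyelinatedMix = data.frame(
                             weight = 1, meanlog = log(1.0), sdlog = 0.3),
                           gRatioMean = 0.6, gRatioSd = 0.08,
                           gRatioRange = c(0.4, 0.9), seed = 1L) {
  for (mix in list(myelinatedMix, unmyelinatedMix)) {
    if (!all(c("weight", "meanlog", "sdlog") %in% names(mix)))
      stop("mixture needs columns weight, meanlog, sdlog")
    if (abs(sum(mix$weight) - 1) > 1e-9)
      stop("mixture weights must sum to 1")
    if (any(mix$sdlog <= 0)) stop("mixture sdlog must be > 0")
  }
  if (nMyelinated < 0 || nUnmyelinated < 0) stop("counts must be >= 0")
  structure(list(nMyelinated = as.integer(nMyelinated),
                 nUnmyelinated = as.integer(nUnmyelinated),
                 myelinatedMix = myelinatedMix,
                 unmyelinatedMix = unmyelinatedMix,
                 gRatioMean = gRatioMean, gRatioSd = gRatioSd,
                 gRatioRange = gRatioRange, seed = as.integer(seed)),
            class = "PopulationSpec")
}

.rtruncnorm <- function(n, mean, sd, lo, hi) {
  out <- numeric(0L)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x > lo & x < hi])
  }
  out[seq_len(n)]
}

.drawMixture <- function(n, mix) {
  if (n == 0L) return(data.frame(component = integer(), diameter = numeric()))
  comp <- sample.int(nrow(mix), n, replace = TRUE, prob = mix$weight)
  data.frame(component = comp,
             diameter = stats::rlnorm(n, mix$meanlog[comp], mix$sdlog[comp]))
}

## draws from the current RNG stream (no reseeding) — used by the section
## generator so all randomness flows from one seed
.drawPopulation <- function(spec) {
  my <- .drawMixture(spec$nMyelinated, spec$myelinatedMix)
  um <- .drawMixture(spec$nUnmyelinated, spec$unmyelinatedMix)
  g <- if (spec$nMyelinated > 0)
    .rtruncnorm(spec$nMyelinated, spec$gRatioMean, spec$gRatioSd,
                spec$gRatioRange[1L], spec$gRatioRange[2L]) else numeric()
  rbind(
    if (nrow(my)) data.frame(category = "myelinated", component = my$component,
                             diameter_um = my$diameter, g_ratio = g),
    if (nrow(um)) data.frame(category = "unmyelinated",
                             component = um$component,
                             diameter_um = um$diameter, g_ratio = NA_real_))
}

#' Sample a fiber population
#'
#' Draws diameters from the configured lognormal mixtures and G-ratios from
#' the truncated normal, reproducibly from the spec's seed. The component
#' labels are retained as ground truth for oracle tests.
#'
#' @param spec a [populationSpec()].
#' @return data.frame (category, component, diameter_um, g_ratio).
#' @export
#' @examples
#' pop <- samplePopulation(populationSpec(nMyelinated = 10, nUnmyelinated = 5))
#' table(pop$category)
samplePopulation <- function(spec) {
  stopifnot(inherits(spec, "PopulationSpec"))
  set.seed(spec$seed)
  out <- .drawPopulation(spec)
  if (is.null(out))
    out <- data.frame(category = character(), component = integer(),
                      diameter_um = numeric(), g_ratio = numeric())
  out
}

#' Cross-section layout specification
#'
#' @param nFascicles number of fascicles.
#' @param side,sex,donorId donor metadata.
#' @param circumferences target outer circumferences per fascicle,
#'   micrometres; `NULL` auto-sizes each fascicle to its fiber load.
#' @param endoRatio target endoneurium/fascicle area ratio(s), recycled.
#' @param subfascicleProb probability that a fascicle is divided into
#'   sub-fascicles.
#' @param nSubfascicles explicit sub-fascicle count per fascicle (recycled;
#'   overrides the probability), or `NULL` to draw 2-3 with
#'   `subfascicleProb`.
#' @param packingFraction target fiber area fraction of the endoneurium used
#'   when auto-sizing (dart-throwing stays reliable up to about 0.35).
#' @param fascicleAspect minor/major axis ratio of fascicle outlines.
#' @param renderFibers set `FALSE` to generate fascicle shells only (fiber
#'   draws still recorded in the ground truth) — used for large cohort
#'   ensembles where per-fiber geometry is not needed.
#' @param seed RNG seed; all randomness in [generateCrossSection()] flows
#'   from it.
#' @return A list of class `SectionSpec`.
#' @export
sectionSpec <- function(nFascicles = 1L, side = "unknown", sex = "unknown",
                        donorId = "synthetic", circumferences = NULL,
                        endoRatio = 0.78, subfascicleProb = 0,
                        nSubfascicles = NULL, packingFraction = 0.3,
                        fascicleAspect = 0.85, renderFibers = TRUE,
                        seed = 1L) {
  if (subfascicleProb < 0 || subfascicleProb > 1)
    stop("subfascicleProb must be in [0, 1]")
  if (!is.null(circumferences) && any(circumferences <= 0))
    stop("circumferences must be > 0")
  if (any(endoRatio <= 0 | endoRatio >= 1))
    stop("endoRatio must be in (0, 1)")
  if (packingFraction <= 0 || packingFraction > 0.5)
    stop("packingFraction must be in (0, 0.5]")
  structure(list(nFascicles = as.integer(nFascicles), side = side, sex = sex,
                 donorId = donorId, circumferences = circumferences,
                 endoRatio = endoRatio, subfascicleProb = subfascicleProb,
                 nSubfascicles = nSubfascicles,
                 packingFraction = packingFraction,
                 fascicleAspect = fascicleAspect,
                 renderFibers = isTRUE(renderFibers), seed = as.integer(seed)),
            class = "SectionSpec")
}

## unit fiber shape: smoothly perturbed ellipse (oblique-section emulation),
## scale-calibrated so the polygon's SAE diameter is exactly `diameter`.
.fiberShape <- function(diameter, nVert = 64L, aspectRange = c(0.75, 1)) {
  t <- stats::runif(1L, aspectRange[1L], aspectRange[2L])
  ang <- stats::runif(1L, 0, 2 * pi)
  phi <- stats::runif(1L, 0, 2 * pi)
  th <- 2 * pi * (seq_len(nVert) - 1L) / nVert
  ripple <- 1 + 0.005 * cos(3 * th + phi)
  x <- (1 / sqrt(t)) * cos(th) * ripple
  y <- sqrt(t) * sin(th) * ripple
  ca <- cos(ang); sa <- sin(ang)
  v <- cbind(x * ca - y * sa, x * sa + y * ca)
  a <- abs(polygonSignedArea(v)); p <- polygonPerimeter(v)
  s <- diameter / saeDiameter(a, p)
  v * s
}

## dart-throwing circle packing inside a polygon; deterministic given the
## RNG state. radii placed in decreasing order; returns centers in the
## original order of `radii`.
.packCircles <- function(radii, poly, retries = 1000L, gap = 0.02) {
  n <- length(radii)
  if (n == 0L) return(matrix(numeric(), 0L, 2L))
  ord <- order(radii, decreasing = TRUE)
  bb <- apply(poly, 2L, range)
  cx <- numeric(n); cy <- numeric(n); rr <- numeric(n)
  placed <- 0L
  for (i in ord) {
    r <- radii[i] * (1 + gap)
    ok <- FALSE
    for (try in seq_len(retries)) {
      px <- stats::runif(1L, bb[1L, 1L], bb[2L, 1L])
      py <- stats::runif(1L, bb[1L, 2L], bb[2L, 2L])
      if (!pointsInPolygon(c(px, py), poly)) next
      if (distanceToBoundary(c(px, py), poly) < r) next
      if (placed > 0L) {
        d2 <- (cx[seq_len(placed)] - px)^2 + (cy[seq_len(placed)] - py)^2
        if (any(d2 < (rr[seq_len(placed)] + r)^2)) next
      }
      ok <- TRUE
      break
    }
    if (!ok)
      stop("packing failed after ", retries, " retries per fiber; ",
           "lower the density (packingFraction) or enlarge the fascicle")
    placed <- placed + 1L
    cx[placed] <- px; cy[placed] <- py; rr[placed] <- r
  }
  centers <- matrix(NA_real_, n, 2L)
  centers[ord, ] <- cbind(cx, cy)[seq_len(n), , drop = FALSE]
  centers
}

## radius of a circular region that dart-throwing can reliably fill with
## circles of the given radii at packing fraction pf; the max(r) term covers
## the boundary margin that dominates for few-fiber groups
.requiredRadius <- function(reff, pf) {
  if (!length(reff)) return(5)
  sqrt(sum(reff^2) * 1.05 / pf) + 1.2 * max(reff)
}

## fascicle shell: perturbed ellipse polygon; inner = outer scaled by
## sqrt(ratio) about the centroid, so area ratio is exact.
.fascicleShell <- function(circumference, aspect, nVert = 128L) {
  ang <- stats::runif(1L, 0, pi)
  phi <- stats::runif(1L, 0, 2 * pi)
  th <- 2 * pi * (seq_len(nVert) - 1L) / nVert
  ripple <- 1 + 0.01 * cos(4 * th + phi)
  x <- (1 / sqrt(aspect)) * cos(th) * ripple
  y <- sqrt(aspect) * sin(th) * ripple
  ca <- cos(ang); sa <- sin(ang)
  v <- cbind(x * ca - y * sa, x * sa + y * ca)
  v * (circumference / polygonPerimeter(v))
}

.scaleAbout <- function(v, s, center = polygonCentroid(v)) {
  sweep(sweep(v, 2L, center, "-") * s, 2L, center, "+")
}

#' Generate a synthetic nerve cross-section
#'
#' Builds fascicle outer/inner perineurium contours as smoothly perturbed
#' ellipses achieving the target endoneurium/fascicle area ratio exactly,
#' draws a fiber population per fascicle, renders each fiber as a perturbed
#' ellipse polygon whose SAE diameter equals the drawn diameter, places
#' fibers by dart throwing without overlap (myelin outer enclosures
#' disjoint), optionally inserts disjoint sub-fascicle compartments, and
#' emits Schwann-cell nuclei as simple ellipses for format completeness.
#' Fascicles are laid out left-to-right with a fixed gap so outer polygons
#' never overlap.
#'
#' All randomness flows from `section$seed`; the same spec yields an
#' identical section. The returned ground-truth ledger records every drawn
#' value.
#'
#' @param section a [sectionSpec()].
#' @param populations a single [populationSpec()] recycled over fascicles,
#'   or a list with one spec per fascicle.
#' @return List with elements `section` (a
#'   [`NerveCrossSection-class`]) and `truth` (list of data.frames
#'   `fibers` and `fascicles` recording the drawn values).
#' @export
#' @examples
#' gen <- generateCrossSection(sectionSpec(seed = 7),
#'                             populationSpec(nMyelinated = 5,
#'                                            nUnmyelinated = 10))
#' gen$section
generateCrossSection <- function(section, populations = populationSpec()) {
  stopifnot(inherits(section, "SectionSpec"))
  nf <- section$nFascicles
  if (inherits(populations, "PopulationSpec"))
    populations <- rep(list(populations), nf)
  if (length(populations) != nf)
    stop("need one population spec per fascicle")
  set.seed(section$seed)
  ratios <- rep_len(section$endoRatio, nf)
  circs <- if (is.null(section$circumferences)) rep(NA_real_, nf) else
    rep_len(section$circumferences, nf)
  nSub <- if (is.null(section$nSubfascicles)) {
    vapply(seq_len(nf), function(i)
      if (stats::runif(1L) < section$subfascicleProb)
        sample(2:3, 1L) else 0L, integer(1L))
  } else as.integer(rep_len(section$nSubfascicles, nf))

  fascicleList <- vector("list", nf)
  truthFibers <- list()
  truthFasc <- list()

  for (fi in seq_len(nf)) {
    fid <- sprintf("F%d", fi)
    pop <- .drawPopulation(populations[[fi]])
    if (is.null(pop))
      pop <- data.frame(category = character(), component = integer(),
                        diameter_um = numeric(), g_ratio = numeric())
    render <- section$renderFibers && nrow(pop) > 0L

    ## fiber shapes (unit geometry before placement)
    shapes <- list(); reff <- numeric(0L)
    if (render) {
      shapes <- vector("list", nrow(pop))
      reff <- numeric(nrow(pop))
      for (i in seq_len(nrow(pop))) {
        shapes[[i]] <- .fiberShape(pop$diameter_um[i])
        reff[i] <- sqrt(max(rowSums(shapes[[i]]^2)))
      }
    }

    ## sub-fascicle group assignment first: it feeds the shell sizing
    k <- nSub[fi]
    grp <- integer(0L)
    subR <- numeric(0L)
    if (k > 0L && render) {
      grp <- sample.int(k, nrow(pop), replace = TRUE)
      subR <- vapply(seq_len(k), function(g)
        .requiredRadius(reff[grp == g], section$packingFraction),
        numeric(1L))
    }

    ## shell sizing; when auto-sized the endoneurium gets enough area for
    ## the fiber load (plus compartment overhead when sub-divided)
    ratio <- ratios[fi]
    if (is.na(circs[fi])) {
      innerArea <- if (k > 0L && render)
        sum(pi * (subR * 1.05)^2) / 0.25
      else if (render)
        pi * .requiredRadius(reff, section$packingFraction)^2 /
          section$fascicleAspect
      else 0
      innerArea <- max(innerArea, 2000)
      ## perimeter of the equal-area ellipse at the configured aspect
      aIn <- sqrt(innerArea / (pi * section$fascicleAspect))
      bIn <- aIn * section$fascicleAspect
      circ <- ellipsePerimeter(aIn, bIn) / sqrt(ratio)
    } else circ <- circs[fi]
    outerV <- .fascicleShell(circ, section$fascicleAspect)
    innerV <- .scaleAbout(outerV, sqrt(ratio), c(0, 0))

    subShells <- list()
    if (k > 0L) {
      ## disjoint circular sub-compartments inside the inner perineurium
      aIn <- sqrt(abs(polygonSignedArea(innerV)) / pi)
      if (!render) subR <- rep(0.28 * aIn, k)
      centers <- .packCircles(subR, .scaleAbout(innerV, 0.97, c(0, 0)),
                              gap = 0.05)
      for (g in seq_len(k)) {
        sid <- sprintf("%s.S%d", fid, g)
        ov <- .fascicleShell(2 * pi * subR[g], 0.97)
        ov <- sweep(ov, 2L, centers[g, ], "+")
        subShells[[g]] <- list(
          id = sid,
          outer = Contour(ov, "subfascicle_perineurium",
                          paste0(sid, ".PA"), fid),
          inner = Contour(.scaleAbout(ov, 0.94), "subfascicle_perineurium",
                          paste0(sid, ".PB"), fid),
          my = list(), um = list())
      }
    } else grp <- integer(0L)

    ## place fibers
    my <- list(); um <- list()
    if (render) {
      wid <- max(3L, nchar(as.character(nrow(pop))))
      placeGroup <- function(idxs, poly) {
        if (!length(idxs)) return(NULL)
        .packCircles(reff[idxs], poly)
      }
      if (k > 0L) {
        centersAll <- matrix(NA_real_, nrow(pop), 2L)
        for (g in seq_len(k)) {
          idxs <- which(grp == g)
          if (length(idxs))
            centersAll[idxs, ] <- placeGroup(
              idxs, .scaleAbout(subShells[[g]]$inner@vertices, 0.98))
        }
      } else {
        centersAll <- matrix(NA_real_, nrow(pop), 2L)
        centersAll[seq_len(nrow(pop)), ] <-
          placeGroup(seq_len(nrow(pop)), .scaleAbout(innerV, 0.98, c(0, 0)))
      }
      mj <- 0L; uj <- 0L
      for (i in seq_len(nrow(pop))) {
        v <- sweep(shapes[[i]], 2L, centersAll[i, ], "+")
        if (pop$category[i] == "myelinated") {
          mj <- mj + 1L
          eid <- sprintf("%s.M%0*d", fid, wid, mj)
          outC <- Contour(v, "myelin_outer", paste0(eid, ":out"))
          innC <- Contour(
            sweep(shapes[[i]] * pop$g_ratio[i], 2L, centersAll[i, ], "+"),
            "myelin_inner", paste0(eid, ":in"), paste0(eid, ":out"))
          f <- MyelinatedFiber(outC, innC)
          if (k > 0L) subShells[[grp[i]]]$my <-
              c(subShells[[grp[i]]]$my, f) else my <- c(my, f)
        } else {
          uj <- uj + 1L
          eid <- sprintf("%s.U%0*d", fid, wid, uj)
          f <- UnmyelinatedFiber(Contour(v, "unmyelinated_axon", eid))
          if (k > 0L) subShells[[grp[i]]]$um <-
              c(subShells[[grp[i]]]$um, f) else um <- c(um, f)
        }
        truthFibers[[length(truthFibers) + 1L]] <- data.frame(
          entity_id = if (pop$category[i] == "myelinated")
            sprintf("%s.M%0*d", fid, wid, mj) else
            sprintf("%s.U%0*d", fid, wid, uj),
          fascicle_id = fid,
          subfascicle_id = if (k > 0L) sprintf("%s.S%d", fid, grp[i]) else
            NA_character_,
          category = pop$category[i], component = pop$component[i],
          diameter_um = pop$diameter_um[i], g_ratio = pop$g_ratio[i],
          x = centersAll[i, 1L], y = centersAll[i, 2L],
          stringsAsFactors = FALSE)
      }
    }

    ## Schwann-cell nuclei: simple ellipses, format completeness only
    nNuc <- if (render) max(1L, round(nrow(pop) / 15)) else 0L
    nuclei <- list()
    if (nNuc > 0L) {
      npos <- matrix(c(stats::runif(nNuc, -0.5, 0.5),
                       stats::runif(nNuc, -0.5, 0.5)), ncol = 2L)
      aInn <- sqrt(abs(polygonSignedArea(innerV)) / pi)
      for (j in seq_len(nNuc)) {
        ctr <- npos[j, ] * aInn * 0.8
        if (!pointsInPolygon(ctr, innerV)) ctr <- c(0, 0) + ctr * 0.2
        nuclei[[j]] <- Contour(
          ellipsePolygon(24L, 2.2, 1.3, center = ctr,
                         angle = stats::runif(1L, 0, pi)),
          "schwann_nucleus", sprintf("%s.N%02d", fid, j))
      }
    }

    subs <- lapply(subShells, function(s)
      Fascicle(s$id, s$outer, s$inner, myelinated = s$my,
               unmyelinated = s$um))
    fa <- Fascicle(fid,
                   Contour(outerV, "perineurium_outer", paste0(fid, ".PO")),
                   Contour(innerV, "perineurium_inner", paste0(fid, ".PI")),
                   subfascicles = subs, myelinated = my, unmyelinated = um,
                   nuclei = nuclei)
    fascicleList[[fi]] <- fa
    truthFasc[[fi]] <- data.frame(
      fascicle_id = fid, circumference = circ, endo_ratio = ratio,
      n_myelinated = sum(pop$category == "myelinated"),
      n_unmyelinated = sum(pop$category == "unmyelinated"),
      n_subfascicles = k, rendered = render, stringsAsFactors = FALSE)
  }

  ## left-to-right layout with a fixed gap; outer polygons cannot overlap
  cursor <- 0
  for (fi in seq_len(nf)) {
    fa <- fascicleList[[fi]]
    bb <- range(fa@outer@vertices[, 1L])
    shift <- c(cursor - bb[1L], 0)
    fascicleList[[fi]] <- .translateFascicle(fa, shift)
    if (length(truthFibers)) {
      sel <- vapply(truthFibers, function(d)
        d$fascicle_id == fa@id, logical(1L))
      for (ii in which(sel)) {
        truthFibers[[ii]]$x <- truthFibers[[ii]]$x + shift[1L]
        truthFibers[[ii]]$y <- truthFibers[[ii]]$y + shift[2L]
      }
    }
    cursor <- cursor + diff(bb) + 25
  }

  xs <- NerveCrossSection(fascicleList, donorId = section$donorId,
                          side = section$side, sex = section$sex)
  truth <- list(
    fibers = if (length(truthFibers)) do.call(rbind, truthFibers) else
      data.frame(entity_id = character(), fascicle_id = character(),
                 subfascicle_id = character(), category = character(),
                 component = integer(), diameter_um = numeric(),
                 g_ratio = numeric(), x = numeric(), y = numeric()),
    fascicles = do.call(rbind, truthFasc))
  list(section = xs, truth = truth)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.translateContour <- function(cn, shift) {
  Contour(sweep(cn@vertices, 2L, shift, "+"), cn@role, cn@entityId,
          cn@parentId)
}

.translateFascicle <- function(fa, shift) {
  tF <- function(f) {
    if (methods::is(f, "MyelinatedFiber"))
      MyelinatedFiber(.translateContour(f@outer, shift),
                      .translateContour(f@inner, shift))
    else UnmyelinatedFiber(.translateContour(f@outline, shift))
  }
  Fascicle(fa@id, .translateContour(fa@outer, shift),
           .translateContour(fa@inner, shift),
           subfascicles = lapply(fa@subfascicles, .translateFascicle, shift),
           myelinated = lapply(fa@myelinated, tF),
           unmyelinated = lapply(fa@unmyelinated, tF),
           nuclei = lapply(fa@nuclei, .translateContour, shift))
}

#' Preset synthetic sections
#'
#' Canned study conditions: `"small-fascicle"` (one fascicle with 11
#' myelinated and 28 unmyelinated fibers, unimodal small-caliber mix),
#' `"large-fascicle"` (221 myelinated, 467 unmyelinated, bimodal myelinated
#' mix), and `"bilateral-cohort"` (27 donors, 14 male and 13 female, left
#' and right sections with right-dominant fascicle counts, side-specific
#' circumference and endoneurium-ratio distributions and a 15.5%
#' sub-fascicle probability; fascicle shells only, with per-fascicle fiber
#' counts drawn log-uniformly within the reported 4-3311 / 21-15646 ranges
#' and recorded in the ground truth).
#'
#' @param preset preset name.
#' @param seed integer seed.
#' @return For the fascicle presets, the `list(section, truth)` of
#'   [generateCrossSection()]; for `"bilateral-cohort"`, a list of such
#'   entries (one per donor side).
#' @export
presetSection <- function(preset = c("small-fascicle", "large-fascicle",
                                     "bilateral-cohort"), seed = 1L) {
  preset <- match.arg(preset)
  if (preset == "small-fascicle") {
    pop <- populationSpec(
      nMyelinated = 11L, nUnmyelinated = 28L,
      myelinatedMix = data.frame(weight = 1, meanlog = log(2.2), sdlog = 0.2),
      seed = seed)
    return(generateCrossSection(
      sectionSpec(1L, donorId = "synthetic-small", seed = seed), pop))
  }
  if (preset == "large-fascicle") {
    pop <- populationSpec(nMyelinated = 221L, nUnmyelinated = 467L,
                          seed = seed)
    return(generateCrossSection(
      sectionSpec(1L, donorId = "synthetic-large", seed = seed), pop))
  }
  ## bilateral cohort
  set.seed(seed)
  nDonor <- 27L
  sexes <- rep(c("male", "female"), c(14L, 13L))
  out <- list()
  fcMeans <- list(male = c(left = 2.9, right = 7.9),
                  female = c(left = 8.6, right = 17.1))
  for (d in seq_len(nDonor)) {
    for (side in c("left", "right")) {
      nf <- max(1L, stats::rpois(1L, fcMeans[[sexes[d]]][[side]]))
      ## side-specific circumference lognormals chosen to match the
      ## reported per-fascicle means (~930 right, ~1170 left, um) while
      ## keeping the pooled first quartile below 300 um
      if (side == "right") {
        circ <- stats::rlnorm(nf, log(480), 1.2)
        ratio <- pmin(0.95, pmax(0.4, stats::rnorm(nf, 0.76, 0.06)))
      } else {
        circ <- stats::rlnorm(nf, log(660), 1.1)
        ratio <- pmin(0.95, pmax(0.4, stats::rnorm(nf, 0.81, 0.05)))
      }
      sp <- sectionSpec(nf, side = side, sex = sexes[d],
                        donorId = sprintf("D%02d", d),
                        circumferences = circ, endoRatio = ratio,
                        subfascicleProb = 0.155, renderFibers = FALSE,
                        seed = sample.int(.Machine$integer.max, 1L))
      gen <- generateCrossSection(
        sp, populationSpec(nMyelinated = 0L, nUnmyelinated = 0L))
      ## census emulation: per-fascicle fiber counts, log-uniform within the
      ## reported ranges (recorded as ground truth; fibers not rendered)
      gen$truth$fascicles$n_myelinated_census <-
        round(exp(stats::runif(nf, log(4), log(3311))))
      gen$truth$fascicles$n_unmyelinated_census <-
        round(exp(stats::runif(nf, log(21), log(15646))))
      out[[sprintf("D%02d_%s", d, side)]] <- gen
    }
  }
  out
}
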