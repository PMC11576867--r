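## Contour-table I/O. One row per vertex with columns
##   entity_id, role, parent_id, fascicle_id, vertex_index, x_um, y_um
## (UTF-8 CSV, header row, '#' comment lines allowed, coordinates written
## with 9 decimal digits). A JSON sidecar (<file>.json with the .csv
## extension replaced) carries donor metadata: donor_id, side, sex.
##
## Conventions:
##  * perineurium_outer / perineurium_inner rows carry their fascicle id in
##    fascicle_id;
##  * a sub-fascicle contributes two subfascicle_perineurium contours sharing
##    the sub-fascicle id in fascicle_id (the larger is the outer border) and
##    naming the parent fascicle in parent_id;
##  * myelin pairing is explicit: a myelin_inner contour names its
##    myelin_outer contour in parent_id; geometric containment is only ever
##    used to verify, never to infer, a pairing;
##  * fibers and nuclei are assigned to fascicles / sub-fascicles by
##    point-in-polygon of their centroid, independent of row order.

.CONTOUR_COLS <- c("entity_id", "role", "parent_id", "fascicle_id",
                   "vertex_index", "x_um", "y_um")

.sidecarPath <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE))
    sub("\\.csv$", ".json", path, ignore.case = TRUE)
  else paste0(path, ".json")
}

#' Read a nerve cross-section from a contour table
#'
#' Parses the contour-table CSV dialect, assembles contours into fibers,
#' sub-fascicles and fascicles, pairs myelin inner/outer contours by
#' `parent_id`, and assigns fibers to (sub-)fascicles by point-in-polygon of
#' their centroid. Donor metadata is taken from the JSON sidecar when
#' present.
#'
#' @param path path to the contour-table CSV.
#' @param dialect format name; only "contour-table" is defined.
#' @return A [`NerveCrossSection-class`].
#' @seealso [writeCrossSection()], [validateCrossSection()]
#' @export
readCrossSection <- function(path, dialect = "contour-table") {
  if (dialect != "contour-table")
    stop("unknown dialect: ", dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missingCols <- setdiff(.CONTOUR_COLS, names(tab))
  if (length(missingCols))
    stop("schema error: missing required column(s): ",
         paste(missingCols, collapse = ", "))
  for (cc in c("entity_id", "role", "parent_id", "fascicle_id"))
    tab[[cc]] <- as.character(tab[[cc]])
  tab$parent_id[tab$parent_id %in% c("", "NA")] <- NA_character_
  tab$fascicle_id[tab$fascicle_id %in% c("", "NA")] <- NA_character_
  bad <- !(tab$role %in% .CONTOUR_ROLES)
  if (any(bad))
    stop("schema error: unknown role '", tab$role[which(bad)[1L]],
         "' for entity ", tab$entity_id[which(bad)[1L]])

  ids <- unique(tab$entity_id)
  ids <- ids[order(ids)]
  contours <- vector("list", length(ids))
  names(contours) <- ids
  meta <- data.frame(entity_id = ids,
                     role = rep(NA_character_, length(ids)),
                     parent_id = rep(NA_character_, length(ids)),
                     fascicle_id = rep(NA_character_, length(ids)),
                     stringsAsFactors = FALSE)
  for (i in seq_along(ids)) {
    rows <- tab[tab$entity_id == ids[i], , drop = FALSE]
    rows <- rows[order(rows$vertex_index), , drop = FALSE]
    if (nrow(rows) < 3L)
      stop("schema error: entity ", ids[i], " has only ", nrow(rows),
           " vertices (at least 3 required)")
    if (length(unique(rows$role)) != 1L)
      stop("schema error: entity ", ids[i], " has conflicting roles")
    contours[[i]] <- Contour(cbind(rows$x_um, rows$y_um), rows$role[1L],
                             ids[i], rows$parent_id[1L])
    meta$role[i] <- rows$role[1L]
    meta$parent_id[i] <- rows$parent_id[1L]
    meta$fascicle_id[i] <- rows$fascicle_id[1L]
  }

  ## ---- fascicles ----
  isPO <- meta$role == "perineurium_outer"
  isPI <- meta$role == "perineurium_inner"
  fascIds <- sort(unique(meta$fascicle_id[isPO | isPI]))
  buildShell <- function(fid) {
    oi <- which(isPO & meta$fascicle_id == fid)
    ii <- which(isPI & meta$fascicle_id == fid)
    if (length(oi) != 1L || length(ii) != 1L)
      stop("fascicle ", fid, " must have exactly one outer and one inner ",
           "perineurium contour")
    list(outer = contours[[oi]], inner = contours[[ii]])
  }

  ## ---- sub-fascicles ----
  isSF <- meta$role == "subfascicle_perineurium"
  sfIds <- sort(unique(meta$fascicle_id[isSF]))
  sfShells <- lapply(sfIds, function(sid) {
    ci <- which(isSF & meta$fascicle_id == sid)
    if (length(ci) != 2L)
      stop("sub-fascicle ", sid, " must have exactly two ",
           "subfascicle_perineurium contours (outer and inner border)")
    areas <- vapply(contours[ci], function(cc)
      abs(polygonSignedArea(cc@vertices)), numeric(1L))
    parent <- unique(stats::na.omit(meta$parent_id[ci]))
    if (length(parent) != 1L)
      stop("sub-fascicle ", sid, " must name its parent fascicle in parent_id")
    list(id = sid, parent = parent,
         outer = contours[[ci[which.max(areas)]]],
         inner = contours[[ci[which.min(areas)]]])
  })
  names(sfShells) <- sfIds

  ## ---- myelinated fibers: explicit parent_id pairing ----
  outIdx <- which(meta$role == "myelin_outer")
  innIdx <- which(meta$role == "myelin_inner")
  innerParent <- meta$parent_id[innIdx]
  if (anyNA(innerParent)) {
    bad <- meta$entity_id[innIdx[which(is.na(innerParent))[1L]]]
    stop("pairing error: myelin_inner contour ", bad,
         " has no parent_id naming its myelin_outer contour")
  }
  myFibers <- list()
  usedOuter <- character()
  for (j in seq_along(innIdx)) {
    oi <- which(meta$entity_id == innerParent[j] & meta$role == "myelin_outer")
    if (length(oi) != 1L)
      stop("pairing error: myelin_inner contour ",
           meta$entity_id[innIdx[j]], " names unknown myelin_outer '",
           innerParent[j], "'")
    myFibers[[length(myFibers) + 1L]] <-
      MyelinatedFiber(contours[[oi]], contours[[innIdx[j]]])
    usedOuter <- c(usedOuter, meta$entity_id[oi])
  }
  orphan <- setdiff(meta$entity_id[outIdx], usedOuter)
  if (length(orphan))
    stop("pairing error: myelin_outer contour ", orphan[1L],
         " has no myelin_inner partner")
  if (length(myFibers))
    myFibers <- myFibers[order(vapply(myFibers, entityId, character(1L)))]

  umFibers <- lapply(which(meta$role == "unmyelinated_axon"),
                     function(i) UnmyelinatedFiber(contours[[i]]))
  if (length(umFibers))
    umFibers <- umFibers[order(vapply(umFibers, entityId, character(1L)))]
  nuclei <- contours[meta$role == "schwann_nucleus"]
  nuclei <- nuclei[order(vapply(nuclei, entityId, character(1L)))]

  ## ---- assemble fascicle shells ----
  shells <- lapply(fascIds, buildShell)
  names(shells) <- fascIds
  buckets <- lapply(fascIds, function(fid)
    list(my = list(), um = list(), nu = list(),
         sub = Filter(function(s) s$parent == fid, sfShells)))
  names(buckets) <- fascIds
  for (fid in fascIds)
    buckets[[fid]]$subMy <- stats::setNames(
      rep(list(list()), length(buckets[[fid]]$sub)),
      vapply(buckets[[fid]]$sub, `[[`, character(1L), "id"))
  for (fid in fascIds)
    buckets[[fid]]$subUm <- buckets[[fid]]$subMy

  assignOne <- function(pt, eid, kind) {
    for (fid in fascIds) {
      if (!pointsInPolygon(pt, shells[[fid]]$inner@vertices)) next
      for (s in buckets[[fid]]$sub) {
        if (pointsInPolygon(pt, s$inner@vertices))
          return(list(fascicle = fid, sub = s$id))
      }
      return(list(fascicle = fid, sub = NA_character_))
    }
    if (kind == "fiber")
      stop("assignment error: fiber ", eid,
           " centroid lies outside every fascicle")
    NULL
  }

  for (f in myFibers) {
    a <- assignOne(matrix(f@centroid, ncol = 2L), entityId(f), "fiber")
    if (is.na(a$sub))
      buckets[[a$fascicle]]$my <- c(buckets[[a$fascicle]]$my, f)
    else
      buckets[[a$fascicle]]$subMy[[a$sub]] <-
        c(buckets[[a$fascicle]]$subMy[[a$sub]], f)
  }
  for (f in umFibers) {
    a <- assignOne(matrix(f@centroid, ncol = 2L), entityId(f), "fiber")
    if (is.na(a$sub))
      buckets[[a$fascicle]]$um <- c(buckets[[a$fascicle]]$um, f)
    else
      buckets[[a$fascicle]]$subUm[[a$sub]] <-
        c(buckets[[a$fascicle]]$subUm[[a$sub]], f)
  }
  for (nc in nuclei) {
    a <- assignOne(matrix(polygonCentroid(nc@vertices), ncol = 2L),
                   entityId(nc), "nucleus")
    if (is.null(a)) {
      warning("nucleus ", entityId(nc), " outside every fascicle; dropped")
    } else {
      buckets[[a$fascicle]]$nu <- c(buckets[[a$fascicle]]$nu, nc)
    }
  }

  fascicleList <- lapply(fascIds, function(fid) {
    b <- buckets[[fid]]
    subs <- lapply(b$sub, function(s)
      Fascicle(s$id, s$outer, s$inner,
               myelinated = b$subMy[[s$id]], unmyelinated = b$subUm[[s$id]]))
    Fascicle(fid, shells[[fid]]$outer, shells[[fid]]$inner,
             subfascicles = unname(subs), myelinated = b$my,
             unmyelinated = b$um, nuclei = b$nu)
  })

  side <- "unknown"; sex <- "unknown"; donor <- "unknown"
  sc <- .sidecarPath(path)
  if (file.exists(sc)) {
    md <- jsonlite::read_json(sc, simplifyVector = TRUE)
    if (!is.null(md$donor_id)) donor <- as.character(md$donor_id)
    if (!is.null(md$side)) side <- md$side
    if (!is.null(md$sex)) sex <- md$sex
  }
  NerveCrossSection(fascicleList, donorId = donor, side = side, sex = sex)
}

.contourRows <- function(cn, fascicleId) {
  v <- cn@vertices
  data.frame(entity_id = cn@entityId, role = cn@role,
             parent_id = ifelse(is.na(cn@parentId), "", cn@parentId),
             fascicle_id = ifelse(is.na(fascicleId), "", fascicleId),
             vertex_index = seq_len(nrow(v)) - 1L,
             x_um = v[, 1L], y_um = v[, 2L], stringsAsFactors = FALSE)
}

#' Write a nerve cross-section as a contour table
#'
#' Emits the CSV dialect read by [readCrossSection()] (coordinates with 9
#' decimal digits; lossless round trip to within 1e-9 micrometres) plus the
#' JSON metadata sidecar.
#'
#' @param xs a [`NerveCrossSection-class`].
#' @param path output CSV path; the sidecar goes to the same path with a
#'   .json extension.
#' @param dialect format name; only "contour-table" is defined.
#' @param comments optional character vector written as leading '#' lines.
#' @return Invisibly, `path`.
#' @export
writeCrossSection <- function(xs, path, dialect = "contour-table",
                              comments = character()) {
  if (dialect != "contour-table") stop("unknown dialect: ", dialect)
  rows <- list()
  add <- function(cn, fid) rows[[length(rows) + 1L]] <<- .contourRows(cn, fid)
  emitFascicle <- function(fa, parent = NA_character_) {
    isSub <- !is.na(parent)
    add(fa@outer, fa@id)
    add(fa@inner, fa@id)
    for (s in fa@subfascicles) emitFascicle(s, fa@id)
    for (f in fa@myelinated) { add(f@outer, NA); add(f@inner, NA) }
    for (f in fa@unmyelinated) add(f@outline, NA)
    for (nc in fa@nuclei) add(nc, NA)
  }
  for (fa in xs@fascicles) emitFascicle(fa)
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(entity_id = character(), role = character(),
               parent_id = character(), fascicle_id = character(),
               vertex_index = integer(), x_um = numeric(), y_um = numeric())
  con <- file(path, open = "wt", encoding = "UTF-8")
  on.exit(close(con))
  for (cm in comments) writeLines(paste0("# ", cm), con)
  writeLines(paste(.CONTOUR_COLS, collapse = ","), con)
  if (nrow(tab))
    writeLines(sprintf("%s,%s,%s,%s,%d,%.9f,%.9f",
                       tab$entity_id, tab$role, tab$parent_id,
                       tab$fascicle_id, tab$vertex_index,
                       tab$x_um, tab$y_um), con)
  jsonlite::write_json(list(donor_id = xs@donorId, side = xs@side,
                            sex = xs@sex),
                       .sidecarPath(path), auto_unbox = TRUE)
  invisible(path)
}

.violation <- function(entity, invariant, message) {
  data.frame(entityId = entity, invariant = invariant, message = message,
             stringsAsFactors = FALSE)
}

#' Validate a nerve cross-section
#'
#' Checks every domain invariant — simple (non-self-intersecting) contours
#' with positive area, myelin inner strictly smaller than and centered
#' inside outer, G-ratio in (0, 1), positive myelin thickness, perineurium
#' inner inside outer, all fiber centroids inside their fascicle's inner
#' perineurium, pairwise-disjoint sub-fascicle regions, and pairwise
#' non-overlapping fascicle outer polygons. Validation reports; it never
#' throws.
#'
#' @param xs a [`NerveCrossSection-class`].
#' @return A data.frame with columns `entityId`, `invariant`, `message`;
#'   zero rows when every invariant holds.
#' @export
validateCrossSection <- function(xs) {
  rep <- list()
  note <- function(v) rep[[length(rep) + 1L]] <<- v

  checkContour <- function(cn) {
    a <- polygonSignedArea(cn@vertices)
    if (abs(a) <= 0)
      note(.violation(cn@entityId, "positive_area", "zero-area contour"))
    if (polygonSelfIntersects(cn@vertices))
      note(.violation(cn@entityId, "simple_polygon",
                      "self-intersecting contour"))
  }

  checkMyelinated <- function(f) {
    eid <- f@outer@entityId
    checkContour(f@outer); checkContour(f@inner)
    ao <- abs(polygonSignedArea(f@outer@vertices))
    ai <- abs(polygonSignedArea(f@inner@vertices))
    if (ai >= ao)
      note(.violation(eid, "inner_lt_outer_area",
                      "myelin inner area not smaller than outer area"))
    cin <- polygonCentroid(f@inner@vertices)
    if (!pointsInPolygon(matrix(cin, ncol = 2L), f@outer@vertices))
      note(.violation(eid, "inner_centroid_inside",
                      "inner centroid outside the outer contour"))
    if (!(f@gRatio > 0 && f@gRatio < 1))
      note(.violation(eid, "g_ratio_range", sprintf(
        "g-ratio %.4g outside (0, 1)", f@gRatio)))
    if (!(f@myelinThickness > 0))
      note(.violation(eid, "myelin_thickness_positive",
                      "non-positive myelin thickness"))
  }

  checkFascicle <- function(fa) {
    checkContour(fa@outer); checkContour(fa@inner)
    ao <- abs(polygonSignedArea(fa@outer@vertices))
    ai <- abs(polygonSignedArea(fa@inner@vertices))
    if (!(ai < ao) ||
        !all(pointsInPolygon(fa@inner@vertices, fa@outer@vertices)))
      note(.violation(fa@id, "perineurium_nested",
                      "inner perineurium not strictly inside outer"))
    fib <- allFibers(fa)
    for (f in fib$myelinated) checkMyelinated(f)
    for (f in fib$unmyelinated) {
      checkContour(f@outline)
      if (!(f@axonDiameter > 0))
        note(.violation(entityId(f), "axon_diameter_positive",
                        "non-positive axon diameter"))
    }
    cents <- rbind(
      if (length(fib$myelinated))
        t(vapply(fib$myelinated, fiberCentroid, numeric(2L))),
      if (length(fib$unmyelinated))
        t(vapply(fib$unmyelinated, fiberCentroid, numeric(2L))))
    if (!is.null(cents) && nrow(cents)) {
      inside <- pointsInPolygon(cents, fa@inner@vertices)
      if (!all(inside)) {
        eids <- c(vapply(fib$myelinated, entityId, character(1L)),
                  vapply(fib$unmyelinated, entityId, character(1L)))
        for (e in eids[!inside])
          note(.violation(e, "fiber_inside_fascicle",
                          sprintf("fiber centroid outside fascicle %s inner perineurium",
                                  fa@id)))
      }
    }
    subs <- fa@subfascicles
    if (length(subs) >= 2L) {
      for (i in seq_len(length(subs) - 1L)) for (j in (i + 1L):length(subs)) {
        if (polygonsOverlap(subs[[i]]@outer@vertices,
                            subs[[j]]@outer@vertices))
          note(.violation(subs[[i]]@id, "subfascicles_disjoint", sprintf(
            "sub-fascicle regions %s and %s overlap",
            subs[[i]]@id, subs[[j]]@id)))
      }
    }
    for (s in subs) checkFascicle(s)
  }

  for (fa in xs@fascicles) checkFascicle(fa)
  fl <- xs@fascicles
  if (length(fl) >= 2L) {
    for (i in seq_len(length(fl) - 1L)) for (j in (i + 1L):length(fl)) {
      if (polygonsOverlap(fl[[i]]@outer@vertices, fl[[j]]@outer@vertices))
        note(.violation(fl[[i]]@id, "fascicles_disjoint", sprintf(
          "fascicle outer polygons %s and %s overlap",
          fl[[i]]@id, fl[[j]]@id)))
    }
  }
  if (length(rep)) do.call(rbind, rep) else
    data.frame(entityId = character(), invariant = character(),
               message = character(), stringsAsFactors = FALSE)
}

#' Flat fiber table of a cross-section or fascicle
#'
#' One row per fiber with its SAE diameter, myelination, location and
#' compartment — the exchange format between the morphometry and the action
#' potential simulation layers.
#'
#' @param x a [`NerveCrossSection-class`] or [`Fascicle-class`].
#' @return data.frame with columns entity_id, fascicle_id, subfascicle_id,
#'   myelinated (logical), diameter (SAE fiber diameter for myelinated
#'   fibers, axon diameter for unmyelinated), axon_diameter, g_ratio, x, y.
#' @export
fiberTable <- function(x) {
  rows <- list()
  addFiber <- function(f, fid, sid) {
    my <- methods::is(f, "MyelinatedFiber")
    rows[[length(rows) + 1L]] <<- data.frame(
      entity_id = entityId(f), fascicle_id = fid, subfascicle_id = sid,
      myelinated = my,
      diameter = if (my) f@fiberDiameter else f@axonDiameter,
      axon_diameter = f@axonDiameter,
      g_ratio = if (my) f@gRatio else NA_real_,
      x = fiberCentroid(f)[1L], y = fiberCentroid(f)[2L],
      stringsAsFactors = FALSE)
  }
  walk <- function(fa, fid = fa@id, sid = NA_character_) {
    for (f in fa@myelinated) addFiber(f, fid, sid)
    for (f in fa@unmyelinated) addFiber(f, fid, sid)
    for (s in fa@subfascicles) walk(s, fid, s@id)
  }
  if (methods::is(x, "NerveCrossSection")) {
    for (fa in x@fascicles) walk(fa)
  } else if (methods::is(x, "Fascicle")) {
    walk(x)
  } else stop("x must be a NerveCrossSection or Fascicle")
  if (!length(rows))
    return(data.frame(entity_id = character(), fascicle_id = character(),
                      subfascicle_id = character(), myelinated = logical(),
                      diameter = numeric(), axon_diameter = numeric(),
                      g_ratio = numeric(), x = numeric(), y = numeric(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  out[order(out$entity_id), , drop = FALSE]
}
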