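## Heuristic single-fiber / compound action potential prediction.
##
## Each fiber contributes a stereotyped extracellular waveform template,
## scaled in amplitude by a power of its SAE diameter, delayed by its
## conduction latency, and widened inversely with its velocity; the CNAP is
## the linear superposition of all single-fiber contributions. Differential
## (bipolar cuff) recordings subtract the waveform seen at the distal
## contact from the proximal one. Units: distance mm, velocity m/s, time ms
## (mm / (m/s) = ms), sampling rate kHz.

#' Conduction velocity from SAE diameter
#'
#' Myelinated fibers follow a linear (Hursh-type) law `v = k * D` on the
#' outer fiber diameter; unmyelinated fibers follow a power law
#' `v = c * d^alpha` on the axon diameter. Both are strictly increasing in
#' diameter.
#'
#' @param diameter SAE diameter(s), micrometres.
#' @param myelinated logical, recycled against `diameter`.
#' @param params a [`FiberModelParams-class`].
#' @return Velocity in m/s.
#' @export
#' @examples
#' conductionVelocity(10, TRUE)    # 60 m/s with the default k = 6
#' conductionVelocity(1, FALSE)    # 1.7 m/s with the defaults c = 1.7, a = 0.5
conductionVelocity <- function(diameter, myelinated,
                               params = fiberModelParams()) {
  if (any(!is.finite(diameter) | diameter <= 0))
    stop("diameters must be positive")
  n <- max(length(diameter), length(myelinated))
  diameter <- rep_len(diameter, n)
  myelinated <- rep_len(as.logical(myelinated), n)
  ifelse(myelinated, params@kMyelinated * diameter,
         params@cUnmyelinated * diameter^params@alphaUnmyelinated)
}

#' Default letter-system fiber class table
#'
#' Velocity intervals (m/s, right-open; a boundary velocity belongs to the
#' faster class) for the classical letter system: myelinated A-alpha
#' \[70, 120), A-beta \[30, 70), A-gamma \[15, 30), A-delta \[3, 15);
#' myelinated preganglionic B \[3, 15); unmyelinated C (0, 3). The
#' boundaries are configuration, not anatomical claims; edit the returned
#' data.frame to change them.
#'
#' @return data.frame with columns label, vMin, vMax, myelinated,
#'   preganglionic.
#' @export
defaultFiberClasses <- function() {
  data.frame(
    label = c("Aalpha", "Abeta", "Agamma", "Adelta", "B", "C"),
    vMin = c(70, 30, 15, 3, 3, 0),
    vMax = c(120, 70, 30, 15, 15, 3),
    myelinated = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    preganglionic = c(FALSE, FALSE, FALSE, FALSE, TRUE, FALSE),
    stringsAsFactors = FALSE)
}

#' Classify a fiber by conduction velocity
#'
#' Returns the unique class whose velocity interval contains the velocity,
#' given the myelination (and optional preganglionic) flag; intervals are
#' right-open so a boundary velocity falls in the faster class. Velocities
#' outside every interval return "unclassified".
#'
#' @param velocity m/s (vectorized).
#' @param myelinated logical, recycled.
#' @param preganglionic logical, recycled; selects the B row of the table
#'   for myelinated fibers in the B velocity range.
#' @param table class table as from [defaultFiberClasses()].
#' @return Character vector of class labels.
#' @export
#' @examples
#' classifyFiber(0.8, FALSE)  # "C"
#' classifyFiber(10, TRUE)    # "Adelta"
#' classifyFiber(10, TRUE, preganglionic = TRUE)  # "B"
classifyFiber <- function(velocity, myelinated, preganglionic = FALSE,
                          table = defaultFiberClasses()) {
  if (any(velocity <= 0)) stop("velocity must be > 0")
  n <- max(length(velocity), length(myelinated), length(preganglionic))
  velocity <- rep_len(velocity, n)
  myelinated <- rep_len(as.logical(myelinated), n)
  preganglionic <- rep_len(as.logical(preganglionic), n)
  vapply(seq_len(n), function(i) {
    cand <- table[table$myelinated == myelinated[i] &
                  table$preganglionic == preganglionic[i], , drop = FALSE]
    ## the lower bound is open only when vMin = 0 (the C class)
    hit <- which(velocity[i] >= cand$vMin & velocity[i] < cand$vMax &
                 !(cand$vMin == 0 & velocity[i] == 0))
    if (length(hit) == 1L) cand$label[hit]
    else if (length(hit) == 0L) "unclassified"
    else stop("class table is ambiguous at v = ", velocity[i], " m/s")
  }, character(1L))
}

## waveform templates on the dimensionless argument u = (t - latency) / width;
## both have their negative main peak exactly at u = 0 so the latency law
## "negative peak at conduction_distance / velocity" holds template-free.
.sfapTemplate <- function(u, template) {
  switch(template,
    gauss_second_derivative = -(1 - u^2) * exp(-u^2 / 2),
    biphasic_sine = ifelse(u >= -1.5 & u <= 0.5, -sin(pi * (u + 0.5)), 0),
    stop("unknown template: ", template))
}

## characteristic waveform width, floored at two sample periods so every
## fiber's waveform is resolvable on the configured grid
.sfapWidth <- function(v, rec, params) {
  pmax(params@durationScale / v, 2 / rec@sampleRate)
}

.autoWindowFor <- function(diameters, myelinated, rec, params) {
  v <- conductionVelocity(diameters, myelinated, params)
  vmin <- min(v)
  (rec@conductionDistance + rec@electrodeSpacing) / vmin +
    5 * .sfapWidth(vmin, rec, params)
}

#' Automatic recording window for a fiber population
#'
#' `(d + s) / v_min + 5 * width(v_min)` milliseconds: long enough to contain
#' the slowest fiber's waveform at the distal contact.
#'
#' @param fibers fiber table (see [fiberTable()]) or numeric diameters with
#'   `myelinated` supplied.
#' @param rec a [`RecordingConfig-class`].
#' @param params a [`FiberModelParams-class`].
#' @param myelinated logical vector when `fibers` is numeric.
#' @return Window length in ms.
#' @export
autoWindow <- function(fibers, rec, params = fiberModelParams(),
                       myelinated = NULL) {
  if (is.data.frame(fibers))
    .autoWindowFor(fibers$diameter, fibers$myelinated, rec, params)
  else .autoWindowFor(fibers, myelinated, rec, params)
}

.timeGrid <- function(rec, window) {
  dt <- 1 / rec@sampleRate
  seq(0, by = dt, length.out = as.integer(ceiling(window / dt)) + 1L)
}

.sfapSamples <- function(time, diameter, myelinated, rec, params) {
  v <- conductionVelocity(diameter, myelinated, params)
  lat <- rec@conductionDistance / v
  width <- .sfapWidth(v, rec, params)
  p <- if (myelinated) params@ampExpMyelinated else params@ampExpUnmyelinated
  amp <- diameter^p
  s <- amp * .sfapTemplate((time - lat) / width, params@template)
  if (rec@mode == "differential") {
    lat2 <- (rec@conductionDistance + rec@electrodeSpacing) / v
    s <- s - amp * .sfapTemplate((time - lat2) / width, params@template)
  }
  list(samples = s, velocity = v, latency = lat)
}

#' Predicted single-fiber action potential
#'
#' The waveform template centered at latency `conduction_distance /
#' velocity`, with characteristic width `duration_scale / velocity` and peak
#' magnitude proportional to diameter^p. The width is floored at two sample
#' periods so the fastest fibers remain resolvable on the sampling grid
#' (otherwise a sub-sample-wide waveform could fall entirely between
#' samples and its peak would be lost). In differential mode the trace is
#' the proximal-contact waveform minus the distal one,
#' `V(t - d/v) - V(t - (d+s)/v)`. If the configured window cannot contain
#' the waveform it is auto-extended with a warning, never silently
#' truncated.
#'
#' @param diameter SAE diameter, micrometres (or a one-row fiber table).
#' @param myelinated logical.
#' @param rec a [`RecordingConfig-class`].
#' @param params a [`FiberModelParams-class`].
#' @return An [`SFAP-class`].
#' @export
#' @examples
#' s <- sfapWaveform(10, TRUE, recordingConfig(conductionDistance = 10))
#' s@latency  # 10 mm / 60 m/s ~ 0.1667 ms
sfapWaveform <- function(diameter, myelinated = TRUE,
                         rec = recordingConfig(),
                         params = fiberModelParams()) {
  if (is.data.frame(diameter)) {
    stopifnot(nrow(diameter) == 1L)
    myelinated <- diameter$myelinated
    diameter <- diameter$diameter
  }
  need <- .autoWindowFor(diameter, myelinated, rec, params)
  window <- rec@window
  if (is.na(window)) {
    window <- need
  } else if (window < need) {
    warning(sprintf(
      "window %.3g ms too short to contain the waveform; extended to %.3g ms",
      window, need))
    window <- need
  }
  time <- .timeGrid(rec, window)
  r <- .sfapSamples(time, diameter, myelinated, rec, params)
  methods::new("SFAP", diameter = diameter,
               myelinated = as.logical(myelinated), velocity = r$velocity,
               latency = r$latency, time = time, samples = r$samples)
}

## exact 1D contiguous partition minimizing total within-bin sum of squared
## deviations (dynamic program on sorted values; weighted form).
.dpPartition <- function(x, w, k) {
  n <- length(x)
  cw <- c(0, cumsum(w))
  cwx <- c(0, cumsum(w * x))
  cwx2 <- c(0, cumsum(w * x^2))
  ssq <- function(i, j) {  # within-SSQ of x[i..j], vectorized over i
    W <- cw[j + 1L] - cw[i]
    S <- cwx[j + 1L] - cwx[i]
    Q <- cwx2[j + 1L] - cwx2[i]
    pmax(Q - S^2 / W, 0)
  }
  cost <- matrix(Inf, k, n)
  back <- matrix(0L, k, n)
  cost[1L, ] <- ssq(1L, seq_len(n))
  if (k > 1L) for (m in 2L:k) {
    for (j in m:n) {
      i <- m:j  # first index of the last bin
      cand <- cost[m - 1L, i - 1L] + ssq(i, j)
      b <- which.min(cand)
      cost[m, j] <- cand[b]
      back[m, j] <- i[b]
    }
  }
  bounds <- integer(k)  # first index of each bin
  j <- n
  for (m in k:1L) {
    bounds[m] <- if (m == 1L) 1L else back[m, j]
    j <- bounds[m] - 1L
  }
  list(cost = cost[k, n], starts = bounds)
}

#' Diameter binning, automatic or manual
#'
#' Manual mode validates the supplied edges (strictly increasing, covering
#' all diameters). Automatic mode minimizes the total within-bin variance
#' over contiguous partitions of the sorted diameters with an exact dynamic
#' program — deterministic, no seed dependence. Populations larger than 4096
#' are collapsed onto 1024 weighted quantile prototypes before the program.
#'
#' @param diameters numeric vector, micrometres.
#' @param k number of bins (1 to 5).
#' @param mode "auto" or "manual".
#' @param edges bin edges for manual mode (length k + 1).
#' @return A [`FiberBinning-class`]; bins are right-open except the last.
#' @export
#' @examples
#' binFibers(c(rep(1.9, 50), rep(9.2, 50)), k = 2)
binFibers <- function(diameters, k = 5L, mode = c("auto", "manual"),
                      edges = NULL) {
  mode <- match.arg(mode)
  if (!length(diameters)) stop("need at least one diameter")
  if (k < 1L || k > 5L) stop("k must be between 1 and 5")
  if (mode == "manual") {
    if (is.null(edges)) stop("manual mode requires edges")
    if (any(diff(edges) <= 0)) stop("edges must be strictly increasing")
    if (min(diameters) < edges[1L] || max(diameters) > edges[length(edges)])
      stop("manual edges do not cover the data range [",
           signif(min(diameters), 4), ", ", signif(max(diameters), 4), "]")
  } else {
    x <- sort(diameters)
    w <- rep(1, length(x))
    if (length(x) > 4096L) {
      qs <- stats::quantile(x, probs = (seq_len(1024L) - 0.5) / 1024L,
                            type = 1L, names = FALSE)
      tw <- table(qs)
      x <- as.numeric(names(tw))
      w <- as.numeric(tw) * length(diameters) / sum(tw)
    }
    ux <- unique(x)
    kk <- min(k, length(ux))
    if (length(ux) < length(x)) {
      w <- vapply(ux, function(u) sum(w[x == u]), numeric(1L))
      x <- ux
    }
    dp <- .dpPartition(x, w, kk)
    starts <- dp$starts
    inner <- if (kk > 1L)
      vapply(starts[-1L], function(i) (x[i - 1L] + x[i]) / 2, numeric(1L))
    else numeric()
    edges <- c(min(diameters), inner, max(diameters))
    if (edges[length(edges)] <= edges[length(edges) - 1L] ||
        length(unique(edges)) < length(edges))
      edges <- unique(edges)
    if (length(edges) < 2L)
      edges <- c(edges[1L], edges[1L] + max(1e-9, abs(edges[1L]) * 1e-9))
  }
  nb <- length(edges) - 1L
  labels <- sprintf("[%.3g,%.3g%s", edges[-length(edges)], edges[-1L],
                    c(rep(")", nb - 1L), "]"))
  methods::new("FiberBinning", edges = as.numeric(edges), mode = mode,
               labels = labels)
}

.binIndex <- function(d, binning) {
  e <- binning@edges
  i <- findInterval(d, e, rightmost.closed = TRUE)
  i[d == e[length(e)]] <- length(e) - 1L
  i
}

#' Predict a compound nerve action potential
#'
#' Sums the single-fiber waveforms of all supplied fibers on a shared time
#' grid. The per-bin decomposition partitions fibers by diameter bins
#' computed separately for myelinated ("M:") and unmyelinated ("UM:")
#' fibers; the total trace is exactly the sum of the per-bin traces. Peaks
#' are local extrema of the total trace above `peakFraction` of its maximum
#' magnitude. An empty fiber set yields an identically zero trace.
#'
#' @param fibers fiber table (see [fiberTable()]), or a
#'   [`NerveCrossSection-class`] / [`Fascicle-class`].
#' @param rec a [`RecordingConfig-class`]; with `window = NA` the window is
#'   auto-sized to the population (see [autoWindow()]). Pass an explicit
#'   window to compare predictions of different fiber subsets on one grid.
#' @param params a [`FiberModelParams-class`].
#' @param binning `NULL` (automatic, up to `k` bins per category), a single
#'   [`FiberBinning-class`] applied to both categories, or a list with
#'   elements `myelinated` and `unmyelinated`.
#' @param k maximum bins per category for automatic binning.
#' @param peakFraction minimum |amplitude| of a reported peak, as a fraction
#'   of the trace maximum.
#' @return A [`CNAPResult-class`].
#' @export
predictCnap <- function(fibers, rec = recordingConfig(),
                        params = fiberModelParams(), binning = NULL,
                        k = 5L, peakFraction = 0.05) {
  if (!is.data.frame(fibers)) fibers <- fiberTable(fibers)
  n <- nrow(fibers)
  if (n == 0L) {
    window <- if (is.na(rec@window)) 1 else rec@window
    time <- .timeGrid(rec, window)
    return(methods::new("CNAPResult", time = time, total = numeric(length(time)),
                        perBin = matrix(0, length(time), 0L),
                        peaks = data.frame(latency_ms = numeric(),
                                           amplitude = numeric(),
                                           polarity = integer()),
                        rec = rec, nFibers = 0L))
  }
  need <- .autoWindowFor(fibers$diameter, fibers$myelinated, rec, params)
  window <- rec@window
  if (is.na(window)) window <- need
  else if (window < need) {
    warning(sprintf(
      "window %.3g ms too short for the slowest fiber; extended to %.3g ms",
      window, need))
    window <- need
  }
  time <- .timeGrid(rec, window)

  categoryBinning <- function(cat) {
    d <- fibers$diameter[fibers$myelinated == cat]
    if (!length(d)) return(NULL)
    if (is.null(binning))
      binFibers(d, k = min(k, length(unique(d))))
    else if (methods::is(binning, "FiberBinning")) binning
    else if (is.list(binning))
      binning[[if (cat) "myelinated" else "unmyelinated"]]
    else stop("invalid binning argument")
  }
  binM <- categoryBinning(TRUE)
  binU <- categoryBinning(FALSE)

  cols <- list()
  addCategory <- function(cat, bn, prefix) {
    idx <- which(fibers$myelinated == cat)
    if (!length(idx)) return()
    bi <- .binIndex(fibers$diameter[idx], bn)
    for (b in seq_along(bn@labels)) {
      sel <- idx[bi == b]
      tr <- numeric(length(time))
      for (i in sel)
        tr <- tr + .sfapSamples(time, fibers$diameter[i],
                                fibers$myelinated[i], rec, params)$samples
      cols[[paste0(prefix, ":", bn@labels[b])]] <<- tr
    }
  }
  addCategory(TRUE, binM, "M")
  addCategory(FALSE, binU, "UM")
  perBin <- do.call(cbind, cols)
  total <- rowSums(perBin)
  peaks <- .findPeaks(time, total, peakFraction)
  methods::new("CNAPResult", time = time, total = total, perBin = perBin,
               peaks = peaks, rec = rec, nFibers = as.integer(n))
}

.findPeaks <- function(time, y, fraction) {
  n <- length(y)
  if (n < 3L || all(y == 0))
    return(data.frame(latency_ms = numeric(), amplitude = numeric(),
                      polarity = integer()))
  thr <- fraction * max(abs(y))
  i <- 2L:(n - 1L)
  isMax <- y[i] > y[i - 1L] & y[i] >= y[i + 1L] & y[i] > thr
  isMin <- y[i] < y[i - 1L] & y[i] <= y[i + 1L] & y[i] < -thr
  sel <- i[isMax | isMin]
  data.frame(latency_ms = time[sel], amplitude = y[sel],
             polarity = ifelse(y[sel] > 0, 1L, -1L))
}

#' Sweep CNAP predictions over conduction distances and electrode spacings
#'
#' One [predictCnap()] call per grid point, deterministic.
#'
#' @param fibers fiber table or domain object, as in [predictCnap()].
#' @param rec base [`RecordingConfig-class`] (mode, sampling, cuff
#'   diameter taken from here).
#' @param distances conduction distances, mm.
#' @param spacings electrode spacings, mm.
#' @param params a [`FiberModelParams-class`].
#' @param ... passed to [predictCnap()].
#' @return Named list of [`CNAPResult-class`], names `"d<dist>_s<spacing>"`.
#' @export
cnapSweep <- function(fibers, rec = recordingConfig(), distances = 10,
                      spacings = 2, params = fiberModelParams(), ...) {
  if (!length(distances) || !length(spacings))
    stop("distance and spacing grids must be non-empty")
  out <- list()
  for (d in distances) for (s in spacings) {
    r <- rec
    r@conductionDistance <- d
    r@electrodeSpacing <- s
    out[[sprintf("d%g_s%g", d, s)]] <- predictCnap(fibers, r, params, ...)
  }
  out
}

#' Velocity-domain transform of a CNAP
#'
#' Re-parameterizes the time axis as `v = conduction_distance / t` (mm / ms
#' = m/s), carrying amplitudes over unchanged; the `t = 0` sample is
#' excluded. Decreasing time maps to increasing velocity.
#'
#' @param cnap a [`CNAPResult-class`].
#' @param rec recording configuration; defaults to the one stored in `cnap`.
#' @return data.frame (velocity_m_s, amplitude) sorted by increasing
#'   velocity.
#' @export
velocityDomain <- function(cnap, rec = NULL) {
  if (is.null(rec)) rec <- cnap@rec
  keep <- cnap@time > 0
  v <- rec@conductionDistance / cnap@time[keep]
  out <- data.frame(velocity_m_s = v, amplitude = cnap@total[keep])
  out[order(out$velocity_m_s), , drop = FALSE]
}

#' Select fibers by region, diameter and myelination
#'
#' Predicates compose by intersection: a fiber is returned iff its centroid
#' lies inside `region` (when given), its relevant SAE diameter falls in
#' `diameterRange` (closed interval, when given) and its myelination matches
#' `myelinated` (when given). An empty selection returns a zero-row table.
#'
#' @param x a [`NerveCrossSection-class`], [`Fascicle-class`] or fiber
#'   table.
#' @param region polygon vertex matrix or [`Contour-class`].
#' @param diameterRange length-2 numeric, micrometres.
#' @param myelinated logical scalar.
#' @return Fiber table subset (see [fiberTable()]).
#' @export
selectFibers <- function(x, region = NULL, diameterRange = NULL,
                         myelinated = NULL) {
  tab <- if (is.data.frame(x)) x else fiberTable(x)
  keep <- rep(TRUE, nrow(tab))
  if (!is.null(region)) {
    poly <- if (methods::is(region, "Contour")) region@vertices else
      as.matrix(region)
    keep <- keep & pointsInPolygon(cbind(tab$x, tab$y), poly)
  }
  if (!is.null(diameterRange)) {
    if (length(diameterRange) != 2L || diff(diameterRange) < 0)
      stop("diameterRange must be c(lo, hi) with lo <= hi")
    keep <- keep & tab$diameter >= diameterRange[1L] &
      tab$diameter <= diameterRange[2L]
  }
  if (!is.null(myelinated)) keep <- keep & tab$myelinated == myelinated
  tab[keep, , drop = FALSE]
}
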