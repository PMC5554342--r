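## Wilson-Cowan population dynamics.
##
## Each population follows
##   tau * dA/dt = -(A - baseline) + (1 - A) * F(input)
## with input = selfWeight*A + sum of link inputs + bias + external, and
##   F(x) = logistic(gain*(x - threshold)) - logistic(-gain*threshold)
## (the classical rectified sigmoid, so F(0) = 0 and the rest state is a
## fixed point).  Integration is explicit Euler with clamping to [0, 1].

.wcDefaults <- list(tau = 10, gain = 4, threshold = 0.5,
                    baseline = 0, bias = 0, selfWeight = 0)

#' Wilson-Cowan transfer function
#'
#' Rectified logistic sigmoid used by all populations: the logistic of the
#' thresholded input minus its value at zero input, so that zero input
#' produces zero drive.
#'
#' @param x net input.
#' @param gain sigmoid slope.
#' @param threshold sigmoid midpoint.
#' @return drive in `(-logistic(-gain*threshold), 1 - logistic(-gain*threshold))`.
#' @export
wcSigmoid <- function(x, gain = 4, threshold = 0.5) {
  stats::plogis(gain * (x - threshold)) - stats::plogis(-gain * threshold)
}

#' Create an empty rate network
#'
#' @return a [RateNetwork-class] with no populations.
#' @seealso [addPopulation()], [addLink()], [stepNetwork()], [runNetwork()]
#' @export
RateNetwork <- function() {
  e <- new.env(parent = emptyenv())
  e$n <- 0L
  e$cap <- 64L
  e$ids <- character(64L)
  e$idx <- new.env(parent = emptyenv(), size = 1024L)
  for (f in names(.wcDefaults)) e[[f]] <- numeric(64L)
  e$A <- numeric(64L)
  e$nl <- 0L
  e$lcap <- 256L
  e$lfrom <- integer(256L); e$lto <- integer(256L)
  e$lw <- numeric(256L); e$lgate <- integer(256L)
  e$W <- NULL                     # dense weight matrix cache (to x from)
  new("RateNetwork", env = e)
}

.growPops <- function(e, need) {
  while (e$cap < need) {
    e$cap <- e$cap * 2L
    length(e$ids) <- e$cap
    for (f in c(names(.wcDefaults), "A")) length(e[[f]]) <- e$cap
  }
}

.growLinks <- function(e, need) {
  while (e$lcap < need) {
    e$lcap <- e$lcap * 2L
    for (f in c("lfrom", "lto", "lgate")) length(e[[f]]) <- e$lcap
    length(e$lw) <- e$lcap
  }
}

.popIndex <- function(e, id, what = "population") {
  i <- e$idx[[id]]
  if (is.null(i)) stop("unknown ", what, " id: ", id, call. = FALSE)
  i
}

#' Add a population to a network
#'
#' @param net a [RateNetwork-class].
#' @param id unique population identifier.
#' @param tau time constant (ms).
#' @param gain,threshold sigmoid parameters.
#' @param baseline resting rate in `[0, 1)`.
#' @param bias tonic external input (used e.g. for tonically active
#'   inhibitors in gating circuits).
#' @param selfWeight recurrent excitatory weight (>= 0); values around 2
#'   with the default sigmoid make the population bistable, the mechanism
#'   used for reverberating working-memory activity.
#' @param activity initial activity (defaults to `baseline`).
#' @return `net`, invisibly.
#' @export
addPopulation <- function(net, id, tau = 10, gain = 4, threshold = 0.5,
                          baseline = 0, bias = 0, selfWeight = 0,
                          activity = baseline) {
  e <- net@env
  if (!is.null(e$idx[[id]])) stop("duplicate population id: ", id, call. = FALSE)
  if (tau <= 0) stop("tau must be positive", call. = FALSE)
  if (selfWeight < 0) stop("selfWeight must be >= 0", call. = FALSE)
  i <- e$n + 1L
  .growPops(e, i)
  e$n <- i
  e$ids[i] <- id
  e$idx[[id]] <- i
  e$tau[i] <- tau; e$gain[i] <- gain; e$threshold[i] <- threshold
  e$baseline[i] <- baseline; e$bias[i] <- bias; e$selfWeight[i] <- selfWeight
  e$A[i] <- activity
  e$W <- NULL
  invisible(net)
}

#' Add a link between two populations
#'
#' Plain links always deliver `weight * A(source)`; gated links deliver
#' `weight * A(source) * A(gate)` so that input flows only while the gate
#' population is active.  Negative weights are inhibitory.
#'
#' @param net a [RateNetwork-class].
#' @param from,to population ids.
#' @param weight signed, finite weight.
#' @param gate optional id of a gating population (makes the link gated).
#' @return `net`, invisibly.
#' @export
addLink <- function(net, from, to, weight, gate = NULL) {
  e <- net@env
  if (!is.finite(weight)) stop("link weight must be finite", call. = FALSE)
  fi <- .popIndex(e, from); ti <- .popIndex(e, to)
  gi <- if (is.null(gate)) 0L else .popIndex(e, gate, "gate")
  k <- e$nl + 1L
  .growLinks(e, k)
  e$nl <- k
  e$lfrom[k] <- fi; e$lto[k] <- ti; e$lw[k] <- weight; e$lgate[k] <- gi
  e$W <- NULL
  invisible(net)
}

#' @rdname nPopulations
#' @export
populationIds <- function(net) net@env$ids[seq_len(net@env$n)]

#' Network size and state accessors
#'
#' @param net a [RateNetwork-class].
#' @return `nPopulations`: the number of populations; `populationIds`:
#'   their ids; `activities`: the named current activity vector.
#' @export
nPopulations <- function(net) net@env$n

#' @rdname nPopulations
#' @export
activities <- function(net) {
  e <- net@env
  stats::setNames(e$A[seq_len(e$n)], e$ids[seq_len(e$n)])
}

#' Set activities of selected populations
#'
#' @param net a [RateNetwork-class].
#' @param values named numeric vector of activities in `[0, 1]`.
#' @return `net`, invisibly.
#' @export
setActivities <- function(net, values) {
  e <- net@env
  for (id in names(values)) e$A[.popIndex(e, id)] <- min(1, max(0, values[[id]]))
  invisible(net)
}

.buildW <- function(e) {
  n <- e$n
  W <- matrix(0, n, n)
  gated <- NULL
  if (e$nl > 0L) {
    sel <- seq_len(e$nl)
    plain <- sel[e$lgate[sel] == 0L]
    if (length(plain)) {
      ## parallel links between the same pair must sum, so aggregate
      ## before the matrix assignment (which would otherwise overwrite)
      key <- (e$lto[plain] - 1) * n + e$lfrom[plain]
      agg <- rowsum(e$lw[plain], key)
      k <- as.numeric(rownames(agg))
      W[cbind((k - 1) %/% n + 1, (k - 1) %% n + 1)] <- agg[, 1L]
    }
    g <- sel[e$lgate[sel] != 0L]
    if (length(g))
      gated <- list(from = e$lfrom[g], to = e$lto[g],
                    w = e$lw[g], gate = e$lgate[g])
  }
  diag(W) <- diag(W) + e$selfWeight[seq_len(n)]
  e$W <- W
  e$gated <- gated
  invisible(NULL)
}

## One Euler step on the raw state; ext is a full-length numeric vector.
.stepRaw <- function(e, ext, dt) {
  n <- e$n
  if (is.null(e$W) || nrow(e$W) != n) .buildW(e)
  A <- e$A[seq_len(n)]
  inp <- as.vector(e$W %*% A) + e$bias[seq_len(n)] + ext
  g <- e$gated
  if (!is.null(g)) {
    contrib <- g$w * A[g$from] * A[g$gate]
    agg <- rowsum(contrib, g$to)
    inp[as.integer(rownames(agg))] <- inp[as.integer(rownames(agg))] + agg[, 1L]
  }
  f <- stats::plogis(e$gain[seq_len(n)] * (inp - e$threshold[seq_len(n)])) -
    stats::plogis(-e$gain[seq_len(n)] * e$threshold[seq_len(n)])
  A <- A + (dt / e$tau[seq_len(n)]) *
    (-(A - e$baseline[seq_len(n)]) + (1 - A) * f)
  e$A[seq_len(n)] <- pmin(1, pmax(0, A))
  invisible(NULL)
}

#' Advance a network by one integration step
#'
#' @param net a [RateNetwork-class].
#' @param external named numeric vector of external inputs (missing
#'   populations receive 0); unknown names are an error.
#' @param dt step size (ms), must be positive.
#' @return `net`, invisibly.
#' @export
stepNetwork <- function(net, external = NULL, dt = 1) {
  e <- net@env
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  ext <- numeric(e$n)
  if (length(external)) {
    if (is.null(names(external))) stop("external input must be named", call. = FALSE)
    for (id in names(external)) ext[.popIndex(e, id)] <- external[[id]]
  }
  .stepRaw(e, ext, dt)
  invisible(net)
}

#' Validate a stimulus schedule
#'
#' A stimulus schedule is a data.frame with columns `id`, `onset`, `offset`
#' (ms) and `amplitude`; onsets must precede offsets and stimulus
#' amplitudes must be non-negative.
#'
#' @param schedule data.frame to validate.
#' @return the schedule, invisibly.
#' @export
validateSchedule <- function(schedule) {
  stopifnot(is.data.frame(schedule),
            all(c("id", "onset", "offset", "amplitude") %in% names(schedule)))
  if (nrow(schedule)) {
    if (any(schedule$onset >= schedule$offset))
      stop("schedule onsets must precede offsets", call. = FALSE)
    if (any(schedule$amplitude < 0))
      stop("stimulus amplitudes must be >= 0", call. = FALSE)
  }
  invisible(schedule)
}

#' Run a network under a stimulus schedule
#'
#' Integrates the network for `duration` ms, sampling every `dt`, while
#' applying the scheduled external inputs.  The run is fully deterministic.
#'
#' @param net a [RateNetwork-class].
#' @param schedule data.frame (`id`, `onset`, `offset`, `amplitude`);
#'   amplitudes of sensory stimuli are non-negative, but control projections
#'   (e.g. quenching inhibition from a parser script) may carry negative
#'   amplitudes, so sign is not checked here; use [validateSchedule()] for
#'   user-facing stimulus schedules.
#' @param duration total simulated time (ms); must cover the last offset.
#' @param dt integration step (ms).
#' @return an [ActivityTrace-class] (samples at `0, dt, ..., duration`;
#'   the sample at time t reflects inputs active on `[t-dt, t)`).
#' @export
runNetwork <- function(net, schedule = NULL, duration = NULL, dt = 1) {
  e <- net@env
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  if (is.null(schedule))
    schedule <- data.frame(id = character(), onset = numeric(),
                           offset = numeric(), amplitude = numeric())
  if (is.null(duration)) duration <- if (nrow(schedule)) max(schedule$offset) else 0
  if (nrow(schedule) && duration < max(schedule$offset))
    stop("duration must cover the schedule", call. = FALSE)
  sidx <- vapply(schedule$id, function(id) .popIndex(e, id), integer(1L))
  nSteps <- ceiling(duration / dt - 1e-9)
  times <- seq(0, by = dt, length.out = nSteps + 1L)
  n <- e$n
  out <- matrix(NA_real_, nSteps + 1L, max(n, 0L))
  if (n > 0L) {
    colnames(out) <- e$ids[seq_len(n)]
    out[1L, ] <- e$A[seq_len(n)]
  }
  for (k in seq_len(nSteps)) {
    t0 <- times[k]
    ext <- numeric(n)
    if (nrow(schedule)) {
      act <- schedule$onset <= t0 & t0 < schedule$offset
      if (any(act)) {
        agg <- rowsum(schedule$amplitude[act], sidx[act])
        ext[as.integer(rownames(agg))] <- agg[, 1L]
      }
    }
    if (n > 0L) {
      .stepRaw(e, ext, dt)
      out[k + 1L, ] <- e$A[seq_len(n)]
    }
  }
  new("ActivityTrace", time = times, activity = out)
}

#' Total network activity over time
#'
#' Point-wise sum of the activity of all populations in a trace.
#'
#' @param trace an [ActivityTrace-class].
#' @return numeric vector, one value per sample.
#' @export
totalActivity <- function(trace) {
  if (ncol(trace@activity) == 0L)
    stop("trace is empty", call. = FALSE)
  rowSums(trace@activity)
}

#' Write an activity trace as long-format CSV
#'
#' Columns `time_ms,population_id,activity`.
#'
#' @param trace an [ActivityTrace-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrace <- function(trace, path) {
  ids <- colnames(trace@activity)
  df <- data.frame(
    time_ms = rep(trace@time, times = length(ids)),
    population_id = rep(ids, each = length(trace@time)),
    activity = as.vector(trace@activity))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a network description to JSON
#'
#' Populations (with parameters and current activity) and links are written
#' as a JSON object; [networkFromJSON()] reconstructs an equivalent network.
#'
#' @param net a [RateNetwork-class].
#' @param path optional file; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly if written to file).
#' @export
networkToJSON <- function(net, path = NULL) {
  e <- net@env
  n <- seq_len(e$n)
  pops <- data.frame(id = e$ids[n], tau = e$tau[n], gain = e$gain[n],
                     threshold = e$threshold[n], baseline = e$baseline[n],
                     bias = e$bias[n], selfWeight = e$selfWeight[n],
                     activity = e$A[n])
  nl <- seq_len(e$nl)
  links <- data.frame(from = e$ids[e$lfrom[nl]], to = e$ids[e$lto[nl]],
                      weight = e$lw[nl],
                      gate = ifelse(e$lgate[nl] == 0L, NA_character_,
                                    e$ids[pmax(e$lgate[nl], 1L)]))
  js <- jsonlite::toJSON(list(populations = pops, links = links),
                         dataframe = "rows", na = "null", digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' @rdname networkToJSON
#' @param json JSON string or path to a JSON file.
#' @export
networkFromJSON <- function(json) {
  x <- jsonlite::fromJSON(json)
  net <- RateNetwork()
  for (i in seq_len(nrow(x$populations))) {
    p <- x$populations[i, ]
    addPopulation(net, p$id, tau = p$tau, gain = p$gain,
                  threshold = p$threshold, baseline = p$baseline,
                  bias = p$bias, selfWeight = p$selfWeight,
                  activity = p$activity)
  }
  for (i in seq_len(nrow(x$links))) {
    l <- x$links[i, ]
    gate <- if (is.null(l$gate) || is.na(l$gate)) NULL else l$gate
    addLink(net, l$from, l$to, l$weight, gate = gate)
  }
  net
}

setMethod("show", "RateNetwork", function(object) {
  cat("RateNetwork with", nPopulations(object), "populations and",
      object@env$nl, "links\n")
})

setMethod("show", "ActivityTrace", function(object) {
  cat("ActivityTrace:", ncol(object@activity), "populations,",
      length(object@time), "samples over",
      max(object@time), "ms\n")
})
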