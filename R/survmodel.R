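#' Kaplan-Meier product-limit estimate
#'
#' @param time positive follow-up times (months).
#' @param event 0/1 event indicators (1 = biochemical recurrence).
#' @return data.frame (time, n_risk, n_event, n_censor, survival)
#'   starting from S(0) = 1; the underlying `survfit` object is kept in
#'   the `"fit"` attribute.
#' @export
kaplanMeier <- function(time, event) {
  if (any(time <= 0)) stop("survival times must be positive")
  stopifnot(length(time) == length(event), all(event %in% c(0, 1)))
  fit <- survival::survfit(survival::Surv(time, event) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = c(0, fit$time),
                    n_risk = c(length(time), fit$n.risk),
                    n_event = c(0, fit$n.event),
                    n_censor = c(0, fit$n.censor),
                    survival = c(1, fit$surv))
  attr(out, "fit") <- fit
  out
}

# step-function lookup of S(t) on a kaplanMeier table
.survivalAt <- function(km, t) {
  i <- findInterval(t, km$time)
  km$survival[i]
}

#' Log-rank test between groups
#'
#' @param time,event follow-up times and 0/1 event indicators.
#' @param group group labels (>= 2 non-empty groups).
#' @return list (statistic, df, p.value).
#' @export
logrankTest <- function(time, event, group) {
  group <- as.factor(group)
  if (nlevels(droplevels(group)) < 2)
    stop("log-rank test needs at least two non-empty groups")
  sd <- survival::survdiff(survival::Surv(time, event) ~ group)
  df <- length(sd$n) - 1
  list(statistic = unname(sd$chisq), df = df,
       p.value = pchisq(sd$chisq, df, lower.tail = FALSE))
}

.encodeCox <- function(data, covariates) {
  stopifnot(all(covariates %in% colnames(data)))
  d <- data[, c("time", "event", covariates), drop = FALSE]
  if ("gleason" %in% covariates)
    d$gleason <- factor(d$gleason, levels = c("lt7", "3+4", "4+3", "gt7"))
  if ("stage" %in% covariates)
    d$stage <- factor(d$stage, levels = c("T1-T2", "T3-T4"))
  d
}

#' Cox proportional-hazards model for biochemical recurrence
#'
#' Fits a Cox model by Newton-Raphson on the Breslow partial
#' likelihood, with the DESNT proportion and PSA as continuous
#' covariates and Gleason (<7 reference), stage (T1-T2 reference) and
#' margins (negative reference) as categorical terms -- whichever of
#' these covariates are requested.
#'
#' @param data data.frame with columns time, event and the requested
#'   covariates (e.g. the clinical table joined with the
#'   `desnt_proportion` column of [stratifyCohort()]).
#' @param covariates character vector of covariate column names.
#' @return object of class `lpdCoxModel`: coefficient table with
#'   hazard ratios and 95\% confidence intervals, Breslow baseline
#'   cumulative hazard at zero covariates, training concordance, and
#'   the underlying `coxph` fit.
#' @export
fitCoxModel <- function(data, covariates) {
  d <- .encodeCox(data, covariates)
  cc <- complete.cases(d)
  if (any(!cc)) {
    message("dropping ", sum(!cc), " incomplete case(s)")
    d <- d[cc, , drop = FALSE]
  }
  for (v in covariates) {
    vals <- d[[v]]
    if (length(unique(vals[!is.na(vals)])) < 2)
      stop("covariate '", v, "' is constant")
  }
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covariates, collapse = " + ")))
  fit <- withCallingHandlers(
    survival::coxph(f, data = d, ties = "breslow", x = TRUE,
                    model = TRUE),
    warning = function(w) {
      if (grepl("infinite|did not converge|out of iterations",
                conditionMessage(w)))
        stop("Cox fit failed (separation or non-convergence): ",
             conditionMessage(w))
      invokeRestart("muffleWarning")
    })
  if (sum(d$event) < length(stats::coef(fit)) + 1)
    stop("too few events for the number of covariates")
  beta <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  tab <- data.frame(term = names(beta), coef = unname(beta),
                    se = unname(se), z = unname(beta / se),
                    p = unname(2 * stats::pnorm(-abs(beta / se))),
                    hr = unname(exp(beta)),
                    lower95 = unname(exp(beta - 1.96 * se)),
                    upper95 = unname(exp(beta + 1.96 * se)),
                    row.names = NULL)
  bh <- survival::basehaz(fit, centered = FALSE)
  structure(list(fit = fit, covariates = covariates,
                 coefficients = tab,
                 baseline = data.frame(time = bh$time,
                                       cumhaz = bh$hazard),
                 xRanges = lapply(
                   d[, covariates, drop = FALSE],
                   function(v) if (is.numeric(v)) range(v) else levels(v)),
                 trainC = unname(
                   survival::concordance(fit)$concordance),
                 n = nrow(d), events = sum(d$event)),
            class = "lpdCoxModel")
}

#' @export
print.lpdCoxModel <- function(x, ...) {
  cat("Cox proportional-hazards model (Breslow ties):", x$n,
      "samples,", x$events, "events\n")
  print(x$coefficients, digits = 3)
  cat("training concordance:", format(x$trainC, digits = 4), "\n")
  invisible(x)
}

# linear predictor of an lpdCoxModel on raw covariate data, at the
# zero-covariate baseline (matching basehaz(centered = FALSE))
.coxLinearPredictor <- function(model, data) {
  d <- .encodeCox(data, model$covariates)
  mm <- stats::model.matrix(stats::delete.response(
    stats::terms(model$fit)), data = d)[, -1, drop = FALSE]
  as.numeric(mm %*% stats::coef(model$fit))
}

# H0(t) at the zero-covariate baseline, step interpolation
.baselineCumhaz <- function(model, t) {
  bl <- model$baseline
  i <- findInterval(t, bl$time)
  c(0, bl$cumhaz)[i + 1]
}

#' Predicted survival probabilities from a fitted Cox model
#'
#' @param model an `lpdCoxModel`.
#' @param data data.frame of covariates.
#' @param horizon time (months) at which S(t | x) is evaluated.
#' @return numeric vector of survival probabilities.
#' @export
predictSurvival <- function(model, data, horizon) {
  if (horizon > max(model$baseline$time))
    stop("horizon lies beyond the baseline-hazard support")
  lp <- .coxLinearPredictor(model, data)
  exp(-.baselineCumhaz(model, horizon) * exp(lp))
}

#' Harrell's concordance index
#'
#' Probability that, of a comparable pair under censoring, the subject
#' with the higher risk score fails first; ties in the score count
#' one half.
#'
#' @param risk per-sample risk score (higher = worse prognosis), or an
#'   `lpdCoxModel` together with `data` to score.
#' @param time,event follow-up times and 0/1 event indicators.
#' @param data covariate data when `risk` is a model.
#' @return concordance in [0, 1].
#' @export
concordanceIndex <- function(risk, time, event, data = NULL) {
  if (inherits(risk, "lpdCoxModel")) {
    stopifnot(!is.null(data))
    risk <- .coxLinearPredictor(risk, data)
  }
  cf <- survival::concordance(survival::Surv(time, event) ~ risk,
                              reverse = TRUE)
  counts <- cf$count
  if (sum(counts[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs under censoring")
  unname(cf$concordance)
}

#' Bootstrap optimism-corrected concordance
#'
#' Harrell's optimism procedure: the model specification is refitted on
#' each bootstrap resample, its concordance is computed on the resample
#' and on the original data, and the mean difference (optimism) is
#' subtracted from the apparent concordance (1000 resamples in the
#' reference workflow).
#'
#' @param data data.frame with time, event and covariates.
#' @param covariates covariate names passed to [fitCoxModel()].
#' @param B number of bootstrap resamples (default 1000).
#' @param seed integer seed or `NULL`.
#' @return list (apparent, optimism, corrected, B, skipped).
#' @export
bootstrapValidate <- function(data, covariates, B = 1000L,
                              seed = NULL) {
  stopifnot(B >= 1)
  full <- fitCoxModel(data, covariates)
  apparent <- concordanceIndex(full, data$time, data$event, data)
  .withSeed(seed, {
    opt <- numeric(0); skipped <- 0L
    for (b in seq_len(B)) {
      idx <- sample.int(nrow(data), replace = TRUE)
      db <- data[idx, , drop = FALSE]
      if (sum(db$event) == 0) { skipped <- skipped + 1L; next }
      mb <- tryCatch(suppressMessages(fitCoxModel(db, covariates)),
                     error = function(e) NULL)
      if (is.null(mb)) { skipped <- skipped + 1L; next }
      cBoot <- concordanceIndex(mb, db$time, db$event, db)
      cOrig <- concordanceIndex(mb, data$time, data$event, data)
      opt <- c(opt, cBoot - cOrig)
    }
    if (!length(opt)) stop("every bootstrap resample failed")
    if (skipped)
      message(skipped, " resample(s) skipped (no events or fit failure)")
    list(apparent = apparent, optimism = mean(opt),
         corrected = apparent - mean(opt), B = B, skipped = skipped)
  })
}

#' Calibration of predicted survival at a fixed horizon
#'
#' Samples are binned by their predicted S(t); each bin's mean
#' prediction is compared with the Kaplan-Meier estimate of the bin at
#' the horizon (5 years = 60 months by default).
#'
#' @param model an `lpdCoxModel`.
#' @param data data.frame with time, event and covariates.
#' @param horizon months (default 60).
#' @param nBins number of bins (default 10).
#' @return data.frame (bin, n, predicted, observed, flagged); `flagged`
#'   marks bins with no subject still at risk at the horizon.
#' @export
calibrationAtHorizon <- function(model, data, horizon = 60,
                                 nBins = 10L) {
  if (horizon > max(data$time))
    stop("horizon lies beyond the observed follow-up")
  pred <- predictSurvival(model, data, horizon)
  br <- unique(quantile(pred, probs = seq(0, 1, length.out = nBins + 1)))
  if (length(br) < 3) {
    warning("predictions are (nearly) constant; using a single bin")
    bin <- factor(rep(1L, length(pred)))
  } else {
    bin <- cut(pred, br, include.lowest = TRUE, labels = FALSE)
    bin <- factor(bin)
  }
  out <- do.call(rbind, lapply(levels(bin), function(b) {
    i <- bin == b
    km <- kaplanMeier(data$time[i], data$event[i])
    atRisk <- sum(data$time[i] >= horizon)
    data.frame(bin = as.integer(b), n = sum(i),
               predicted = mean(pred[i]),
               observed = .survivalAt(km, horizon),
               flagged = atRisk == 0)
  }))
  rownames(out) <- NULL
  out
}

#' Build a points-based nomogram from a fitted Cox model
#'
#' Re-parameterises the Cox linear predictor on a 0-100 point scale:
#' the covariate with the largest coefficient-times-range spans exactly
#' 0-100 points, every other covariate is scaled accordingly, and the
#' total point score maps through the Breslow baseline to survival
#' probabilities at the requested horizons (1, 3, 5 and 7 years by
#' default). Predictions are an exact re-parameterisation of the Cox
#' model.
#'
#' @param model an `lpdCoxModel` (fitted with its training ranges
#'   stored).
#' @param horizons months (default c(12, 36, 60, 84)).
#' @param nGrid grid size of the total-points-to-survival tables.
#' @return object of class `lpdNomogram`: per-covariate points maps,
#'   the points-to-linear-predictor map, and per-horizon
#'   total-points-to-survival tables.
#' @export
buildNomogram <- function(model, horizons = c(12, 36, 60, 84),
                          nGrid = 101L) {
  bad <- horizons > max(model$baseline$time)
  if (any(bad))
    stop("horizon(s) beyond the baseline-hazard support: ",
         paste(horizons[bad], collapse = ", "))
  beta <- stats::coef(model$fit)
  asg <- attr(stats::model.matrix(model$fit), "assign")
  if (length(asg) == length(beta) + 1) asg <- asg[-1]  # drop intercept
  terms <- model$covariates
  maps <- list()
  spans <- numeric(length(terms))
  for (j in seq_along(terms)) {
    cols <- which(asg == j)
    v <- model$xRanges[[terms[j]]]
    if (is.character(v)) {                      # factor term
      contrib <- c(0, unname(beta[cols]))      # reference level first
      names(contrib) <- v
      maps[[terms[j]]] <- list(type = "factor", contrib = contrib)
      spans[j] <- max(contrib) - min(contrib)
    } else {                                   # continuous term
      b <- unname(beta[cols])
      contrib <- b * v
      maps[[terms[j]]] <- list(type = "continuous", beta = b,
                               range = v)
      spans[j] <- max(contrib) - min(contrib)
    }
  }
  span <- max(spans)
  if (span <= 0) stop("all covariate contributions are constant")
  lpRef <- 0
  for (j in seq_along(terms)) {
    m <- maps[[terms[j]]]
    lo <- if (m$type == "factor") min(m$contrib) else min(m$beta * m$range)
    lpRef <- lpRef + lo
    maps[[terms[j]]]$points <- if (m$type == "factor")
      100 * (m$contrib - lo) / span
    else NULL
  }
  totalMax <- 100 * sum(spans) / span
  grid <- seq(0, totalMax, length.out = nGrid)
  lpGrid <- lpRef + span * grid / 100
  survTables <- lapply(horizons, function(h) {
    H0 <- .baselineCumhaz(model, h)
    data.frame(points = grid, survival = exp(-H0 * exp(lpGrid)))
  })
  names(survTables) <- paste0("t", horizons)
  structure(list(maps = maps, span = span, lpRef = lpRef,
                 horizons = horizons, survTables = survTables,
                 model = model),
            class = "lpdNomogram")
}

#' Points assigned to covariate values by a nomogram
#'
#' @param nomogram an `lpdNomogram`.
#' @param data data.frame of raw covariate values.
#' @return matrix of per-covariate points plus a `total` column.
#' @export
nomogramPoints <- function(nomogram, data) {
  terms <- names(nomogram$maps)
  pts <- sapply(terms, function(tm) {
    m <- nomogram$maps[[tm]]
    v <- data[[tm]]
    if (m$type == "factor") {
      unname(m$points[as.character(v)])
    } else {
      contrib <- m$beta * v
      100 * (contrib - min(m$beta * m$range)) / nomogram$span
    }
  })
  pts <- matrix(pts, nrow = nrow(data),
                dimnames = list(NULL, terms))
  cbind(pts, total = rowSums(pts))
}

#' Survival probability from a total point score
#'
#' @param nomogram an `lpdNomogram`.
#' @param total total point scores.
#' @param horizon one of the nomogram's horizons (months).
#' @return survival probabilities (exact Cox re-parameterisation, not
#'   interpolated from the printed tables).
#' @export
nomogramSurvival <- function(nomogram, total, horizon) {
  if (!horizon %in% nomogram$horizons)
    stop("horizon must be one of: ",
         paste(nomogram$horizons, collapse = ", "))
  lp <- nomogram$lpRef + nomogram$span * total / 100
  H0 <- .baselineCumhaz(nomogram$model, horizon)
  exp(-H0 * exp(lp))
}

#' @export
print.lpdNomogram <- function(x, ...) {
  cat("Cox nomogram (", paste(x$horizons, collapse = "/"),
      " months)\n", sep = "")
  for (tm in names(x$maps)) {
    m <- x$maps[[tm]]
    if (m$type == "factor") {
      cat(sprintf("  %-10s ", tm))
      cat(paste(sprintf("%s=%.1f", names(m$points), m$points),
                collapse = "  "), "\n")
    } else {
      lo <- min(m$beta * m$range); hi <- max(m$beta * m$range)
      cat(sprintf("  %-10s %.3g -> %.1f pts, %.3g -> %.1f pts\n", tm,
                  m$range[which.min(m$beta * m$range)], 0,
                  m$range[which.max(m$beta * m$range)],
                  100 * (hi - lo) / x$span))
    }
  }
  for (h in names(x$survTables)) {
    st <- x$survTables[[h]]
    sel <- round(seq(1, nrow(st), length.out = 6))
    cat("  S(", sub("t", "", h), " mo): ",
        paste(sprintf("%.0fpts=%.3f", st$points[sel],
                      st$survival[sel]), collapse = "  "), "\n",
        sep = "")
  }
  invisible(x)
}
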