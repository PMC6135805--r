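#' Normalize an Elispot series to the day-1-to-3 maximum
#'
#' Averages spot counts across wells per day, takes the maximum of the day-1,
#' -2 and -3 means as the 100% reference (ties resolved to the earliest day),
#' and expresses every day as a percentage of it.
#'
#' @param series data.frame with columns `day` and `spots` (and optionally
#'   `well`, `condition`).
#' @return data.frame with columns `day`, `meanSpots`, `percent`, carrying
#'   attributes `refDay` and `condition`.
#' @export
normalizeSurvival <- function(series) {
  series <- as.data.frame(series)
  stopifnot(all(c("day", "spots") %in% names(series)))
  agg <- aggregate(spots ~ day, data = series, FUN = mean)
  agg <- agg[order(agg$day), , drop = FALSE]
  refWindow <- agg[agg$day >= 1 & agg$day <= 3, , drop = FALSE]
  if (!nrow(refWindow))
    stop("no observations on days 1-3; cannot set the normalization reference")
  ref <- max(refWindow$spots)
  if (ref == 0)
    stop("reference (maximal day-1-3 mean) is zero: no surviving cells to normalize against")
  refDay <- refWindow$day[which(refWindow$spots == ref)[1]]
  out <- data.frame(day = agg$day, meanSpots = agg$spots,
                    percent = 100 * agg$spots / ref,
                    row.names = NULL)
  attr(out, "refDay") <- refDay
  attr(out, "condition") <- if ("condition" %in% names(series))
    as.character(series$condition[1]) else NA_character_
  out
}

# accept either a raw series (normalized here) or the output of
# normalizeSurvival (recognized by its percent column)
.ensureNormalized <- function(series) {
  if ("percent" %in% names(series)) as.data.frame(series)
  else normalizeSurvival(series)
}

#' Compare two survival series by linear regression with a media covariate
#'
#' Normalizes both series (inputs already carrying a `percent` column are
#' taken as normalized), pools the per-day percentages and fits
#' `percent ~ day + media` by ordinary least squares (optionally
#' `log1p(percent)`); the reported coefficient and p-value belong to the
#' media indicator (series B relative to series A).
#'
#' @param seriesA,seriesB Elispot data.frames (see [normalizeSurvival()]).
#' @param logScale model `log1p(percent)` instead of raw percent.
#' @param includeDay include day as a continuous covariate (default); set
#'   `FALSE` for the plain two-group comparison.
#' @return list with `coefficient`, `p_value`, `refDays` and the fitted `lm`
#'   model.
#' @export
compareMedia <- function(seriesA, seriesB, logScale = FALSE,
                         includeDay = TRUE) {
  na <- .ensureNormalized(seriesA)
  nb <- .ensureNormalized(seriesB)
  if (length(unique(na$day)) < 2 || length(unique(nb$day)) < 2)
    stop("each series needs at least two distinct days; the model is unidentifiable")
  df <- rbind(data.frame(percent = na$percent, day = na$day, media = "A"),
              data.frame(percent = nb$percent, day = nb$day, media = "B"))
  if (nrow(df) < 3) stop("fewer than 3 pooled points; the model is unidentifiable")
  df$media <- factor(df$media, levels = c("A", "B"))
  df$y <- if (logScale) log1p(df$percent) else df$percent
  fit <- if (includeDay) lm(y ~ day + media, data = df)
         else lm(y ~ media, data = df)
  co <- summary(fit)$coefficients
  list(coefficient = unname(co["mediaB", "Estimate"]),
       p_value = unname(co["mediaB", "Pr(>|t|)"]),
       refDays = c(A = attr(na, "refDay"), B = attr(nb, "refDay")),
       model = fit)
}

#' ANOVA across survival conditions
#'
#' Fits fixed-effects models on the normalized percentages: with
#' `dayMatched = TRUE` a two-way model `percent ~ factor(day) + condition`
#' (the condition F-test is reported), otherwise a one-way model on
#' condition alone. Optional BH-adjusted pairwise one-way contrasts.
#'
#' @param seriesList named list of Elispot data.frames.
#' @param dayMatched include day as a fixed effect.
#' @param pairwise also compute all pairwise one-way comparisons with BH
#'   adjustment.
#' @return list with `F_statistic`, `p_value` and (optionally) `pairwise`
#'   (data.frame with `a`, `b`, `F`, `p`, `q`).
#' @export
anovaConditions <- function(seriesList, dayMatched = TRUE, pairwise = FALSE) {
  if (length(seriesList) < 2) stop("need at least two conditions")
  if (is.null(names(seriesList)))
    names(seriesList) <- paste0("cond", seq_along(seriesList))
  norm <- lapply(seriesList, .ensureNormalized)
  df <- do.call(rbind, lapply(names(norm), function(nm)
    data.frame(percent = norm[[nm]]$percent, day = norm[[nm]]$day,
               condition = nm)))
  df$condition <- factor(df$condition)
  fit <- if (dayMatched) lm(percent ~ factor(day) + condition, data = df)
         else lm(percent ~ condition, data = df)
  at <- anova(fit)
  Fst <- at["condition", "F value"]
  p <- at["condition", "Pr(>F)"]
  # all conditions identical: zero between-condition SS
  if (is.na(Fst) || at["condition", "Sum Sq"] < 1e-24) { Fst <- 0; p <- 1 }
  out <- list(F_statistic = Fst, p_value = p)
  if (pairwise) {
    nms <- names(seriesList)
    combos <- utils::combn(nms, 2)
    pw <- data.frame(a = combos[1, ], b = combos[2, ], F = NA_real_,
                     p = NA_real_)
    for (i in seq_len(ncol(combos))) {
      sub <- droplevels(df[df$condition %in% combos[, i], , drop = FALSE])
      f2 <- lm(percent ~ condition, data = sub)
      a2 <- anova(f2)
      pw$F[i] <- a2["condition", "F value"]
      pw$p[i] <- a2["condition", "Pr(>F)"]
      if (is.na(pw$F[i]) || a2["condition", "Sum Sq"] < 1e-24) {
        pw$F[i] <- 0; pw$p[i] <- 1
      }
    }
    pw$q <- bhFdr(pw$p)
    out$pairwise <- pw
  }
  out
}
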