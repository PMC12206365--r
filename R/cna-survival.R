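#' Classify a discrete copy-number level
#'
#' GISTIC discrete levels: 2 = amplification, 1 = gain, 0 = diploid,
#' -1 = shallow deletion, -2 = deep deletion. The loss flag is `level < 0`
#' and the gain flag `level > 0`.
#'
#' @param level integer vector over `{-2, -1, 0, 1, 2}`.
#' @return data.frame with `level`, `category`, `loss`, `gain`.
#' @examples
#' classifyCna(c(-2, -1, 0, 1, 2))
#' @export
classifyCna <- function(level) {
    if (any(!level %in% -2:2, na.rm = TRUE))
        stop("GISTIC level must be in {-2,-1,0,1,2}")
    cat_map <- c(`-2` = "deep_deletion", `-1` = "shallow_deletion",
                 `0` = "diploid", `1` = "gain", `2` = "amplification")
    data.frame(level = level,
               category = unname(cat_map[as.character(level)]),
               loss = level < 0, gain = level > 0)
}

#' Summarize copy-number alterations per cancer type and overall
#'
#' Counts and percentages (one decimal) of loss / diploid / gain samples and
#' the loss:gain ratio (one decimal; `NA`-flagged when there are no gains).
#'
#' @param cna data.frame with `sample_id`, `cancer_type`, `gistic_level`, or
#'   a counts list `list(total =, loss =, gain =)` for printed-table input.
#' @return data.frame with one row per cancer type plus an `overall` row:
#'   `cancer_type`, `n`, `n_loss`, `n_gain`, `n_diploid`, `pct_loss`,
#'   `pct_gain`, `pct_diploid`, `loss_gain_ratio`.
#' @examples
#' cnaSummary(list(total = 10712, loss = 3373, gain = 940))
#' @export
cnaSummary <- function(cna) {
    if (is.list(cna) && !is.data.frame(cna)) {
        n <- cna$total; nl <- cna$loss; ng <- cna$gain
        return(data.frame(
            cancer_type = "overall", n = n, n_loss = nl, n_gain = ng,
            n_diploid = n - nl - ng,
            pct_loss = round(100 * nl / n, 1),
            pct_gain = round(100 * ng / n, 1),
            pct_diploid = round(100 * (n - nl - ng) / n, 1),
            loss_gain_ratio = if (ng > 0) round(nl / ng, 1) else NA_real_,
            stringsAsFactors = FALSE))
    }
    cls <- classifyCna(cna$gistic_level)
    one <- function(type, idx) {
        n <- sum(idx); nl <- sum(cls$loss[idx]); ng <- sum(cls$gain[idx])
        data.frame(cancer_type = type, n = n, n_loss = nl, n_gain = ng,
                   n_diploid = n - nl - ng,
                   pct_loss = round(100 * nl / n, 1),
                   pct_gain = round(100 * ng / n, 1),
                   pct_diploid = round(100 * (n - nl - ng) / n, 1),
                   loss_gain_ratio = if (ng > 0) round(nl / ng, 1) else
                       NA_real_,
                   stringsAsFactors = FALSE)
    }
    types <- sort(unique(cna$cancer_type))
    out <- do.call(rbind, lapply(types, function(tp)
        one(tp, cna$cancer_type == tp)))
    rbind(out, one("overall", rep(TRUE, nrow(cna))))
}

#' Gene-arm co-occurrence fractions
#'
#' Fraction of samples with a gene-level event (loss or gain) that also
#' carry the arm-level event, per cancer type and overall. Samples with a
#' gene event but no arm status are excluded and tallied.
#'
#' @param cna data.frame with `sample_id`, `cancer_type`, `gistic_level`.
#' @param armStatus data.frame with `sample_id`, `arm`, `status`
#'   (`loss` / `unchanged` / `gain`).
#' @param geneEvent,armEvent `"loss"` or `"gain"`.
#' @param arm arm to test (must match `armStatus$arm`).
#' @return data.frame per cancer type plus overall: `cancer_type`,
#'   `n_gene_event`, `n_co`, `fraction` (NA on empty denominator);
#'   attribute `"excluded"` counts samples lacking arm status.
#' @export
cooccurrenceFraction <- function(cna, armStatus, geneEvent = "loss",
                                 armEvent = "loss", arm = NULL) {
    stopifnot(geneEvent %in% c("loss", "gain"),
              armEvent %in% c("loss", "gain"))
    cls <- classifyCna(cna$gistic_level)
    ge <- if (geneEvent == "loss") cls$loss else cls$gain
    as <- armStatus
    if (!is.null(arm)) as <- as[as$arm == arm, , drop = FALSE]
    arm_evt <- as$sample_id[as$status == armEvent]
    has_status <- cna$sample_id %in% as$sample_id
    excluded <- sum(ge & !has_status)
    use <- ge & has_status
    one <- function(type, idx) {
        denom <- sum(use & idx)
        co <- sum(use & idx & cna$sample_id %in% arm_evt)
        data.frame(cancer_type = type, n_gene_event = denom, n_co = co,
                   fraction = if (denom > 0) co / denom else NA_real_,
                   stringsAsFactors = FALSE)
    }
    types <- sort(unique(cna$cancer_type))
    out <- do.call(rbind, lapply(types, function(tp)
        one(tp, cna$cancer_type == tp)))
    out <- rbind(out, one("overall", rep(TRUE, nrow(cna))))
    attr(out, "excluded") <- excluded
    out
}

#' Stratify survival records by gene copy loss
#'
#' Joins CNA calls to survival records: `loss` means one or both gene copies
#' lost (GISTIC level < 0); everything else, gains included, is `wild_type`
#' (the two-group design). Samples present in only one table are excluded
#' and tallied.
#'
#' @param cna data.frame with `sample_id`, `gistic_level`.
#' @param surv data.frame with `sample_id`, `time`, `event` and optional
#'   `endpoint`.
#' @return the survival data.frame with a `group` factor
#'   (`wild_type` / `loss`); attribute `"excluded"` is a named count vector.
#' @export
stratifyByGeneLoss <- function(cna, surv) {
    idx <- match(surv$sample_id, cna$sample_id)
    no_cna <- sum(is.na(idx))
    no_surv <- sum(!cna$sample_id %in% surv$sample_id)
    out <- surv[!is.na(idx), , drop = FALSE]
    lvl <- cna$gistic_level[idx[!is.na(idx)]]
    out$group <- factor(ifelse(lvl < 0, "loss", "wild_type"),
                        levels = c("wild_type", "loss"))
    attr(out, "excluded") <- c(no_cna = no_cna, no_survival = no_surv)
    out
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator via [survival::survfit()] (deaths precede
#' censorings at tied times), returned as a tidy step function per group.
#'
#' @param surv data.frame with `time`, `event` and optional `group`.
#' @return data.frame with `group`, `time`, `n_risk`, `n_event`,
#'   `n_censor`, `survival`.
#' @examples
#' km <- kmEstimate(data.frame(time = c(1, 2, 3),
#'                             event = c(TRUE, FALSE, TRUE)))
#' km$survival   # 2/3 after t=1, 1/3 after t=3
#' @export
kmEstimate <- function(surv) {
    if (!"group" %in% names(surv)) surv$group <- factor("all")
    fit <- survival::survfit(survival::Surv(time, event) ~ group,
                             data = surv)
    sm <- summary(fit, censored = TRUE)
    grp <- if (is.null(sm$strata)) rep("all", length(sm$time)) else
        sub("^group=", "", as.character(sm$strata))
    data.frame(group = grp, time = sm$time, n_risk = sm$n.risk,
               n_event = sm$n.event, n_censor = sm$n.censor,
               survival = sm$surv, stringsAsFactors = FALSE)
}

#' Two-group log-rank test
#'
#' Standard log-rank test (hypergeometric variance, chi-square with 1 df)
#' via [survival::survdiff()]. With no events the statistic is undefined and
#' flagged.
#'
#' @param surv data.frame with `time`, `event`, `group` (two levels).
#' @return list with `chi2`, `p`, `defined`.
#' @export
logrankTest <- function(surv) {
    if (sum(surv$event) == 0L)
        return(list(chi2 = NA_real_, p = NA_real_, defined = FALSE))
    sd <- survival::survdiff(survival::Surv(time, event) ~ group,
                             data = surv)
    chi2 <- sd$chisq
    list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE),
         defined = TRUE)
}
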