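## Delta-delta-Ct relative expression with multi-reference normalization,
## followed by one-way ANOVA and Tukey HSD on the (variance-stabilized)
## delta-Ct values. Amplification efficiency is fixed at 2, the classic
## 2^(-ddCt) method.

#' Delta-delta-Ct relative expression
#'
#' Per (sample, replicate): reference Ct = arithmetic mean of the reference
#' genes' Cts (equivalent to a geometric mean of linear quantities at
#' efficiency 2); dCt = Ct_target - Ct_ref. Per group: ddCt = mean dCt -
#' mean dCt(control); fold change = 2^(-ddCt). Replicate-level fold changes
#' (each replicate's dCt against the control group mean) are retained for
#' dispersion and for the follow-up ANOVA.
#'
#' @param table data.frame as from \code{\link{readQPCRTable}} (columns
#'   sample_id, group, target, reference, replicate, ct).
#' @param target target gene symbol.
#' @param references character vector of reference gene symbols.
#' @param controlGroup label of the control group.
#' @param statsOn "dct" (default) or "fold": scale on which ANOVA/Tukey run.
#' @return list of class "QPCRResult": \code{groups} data.frame (group,
#'   mean_dct, ddct, fold_change, sd_fold, n), \code{replicateFolds} named
#'   list, \code{anova} (F, p), \code{tukey} pairwise data.frame.
#' @export
deltaDeltaCt <- function(table, target, references, controlGroup,
                         statsOn = c("dct", "fold")) {
  statsOn <- match.arg(statsOn)
  if (any(table$ct <= 0)) stop("Ct values must be positive")
  if (!controlGroup %in% table$group)
    stop("control group '", controlGroup, "' not present")
  keys <- unique(table[, c("sample_id", "group", "replicate")])
  dct <- vapply(seq_len(nrow(keys)), function(i) {
    sub <- table[table$sample_id == keys$sample_id[i] &
                 table$replicate == keys$replicate[i], ]
    tgt <- sub$ct[sub$target == target]
    if (length(tgt) != 1L)
      stop("sample '", keys$sample_id[i], "' replicate ",
           keys$replicate[i], ": expected one Ct for target ", target)
    refs <- vapply(references, function(r) {
      v <- sub$ct[sub$target == r]
      if (!length(v))
        stop("missing reference '", r, "' Ct for sample '",
             keys$sample_id[i], "' replicate ", keys$replicate[i])
      mean(v)
    }, numeric(1))
    tgt - mean(refs)
  }, numeric(1))
  keys$dct <- dct
  ctrlMean <- mean(keys$dct[keys$group == controlGroup])
  groups <- unique(c(controlGroup,
                     setdiff(unique(keys$group), controlGroup)))
  repFolds <- lapply(groups, function(g)
    2^(-(keys$dct[keys$group == g] - ctrlMean)))
  names(repFolds) <- groups
  gdf <- do.call(rbind, lapply(groups, function(g) {
    d <- keys$dct[keys$group == g]
    ddct <- mean(d) - ctrlMean
    data.frame(group = g, mean_dct = mean(d), ddct = ddct,
               fold_change = 2^(-ddct),
               sd_fold = stats::sd(2^(-(d - ctrlMean))),
               n = length(d), stringsAsFactors = FALSE)
  }))
  rownames(gdf) <- NULL
  values <- if (statsOn == "dct")
    split(keys$dct, factor(keys$group, levels = groups))
  else repFolds
  at <- anovaTukey(values)
  structure(list(groups = gdf, replicateFolds = repFolds,
                 anova = at[c("F", "p")], tukey = at$tukey,
                 control = controlGroup, target = target,
                 references = references),
            class = "QPCRResult")
}

#' One-way ANOVA with Tukey HSD follow-up
#'
#' @param values named list of numeric vectors, one per group (>= 2 groups,
#'   each >= 2 replicates).
#' @param alpha significance level for the Tukey intervals.
#' @return list with F, p (one-way ANOVA) and \code{tukey}, a data.frame of
#'   pairwise comparisons (comparison, diff, p_adj).
#' @export
anovaTukey <- function(values, alpha = 0.05) {
  if (length(values) < 2) stop("need >= 2 groups")
  if (any(lengths(values) < 2))
    stop("every group needs >= 2 replicates")
  df <- data.frame(
    y = unlist(values, use.names = FALSE),
    g = factor(rep(names(values), lengths(values)),
               levels = names(values)))
  fit <- stats::aov(y ~ g, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$g
  tukey <- data.frame(comparison = rownames(tk),
                      diff = tk[, "diff"], p_adj = tk[, "p adj"],
                      stringsAsFactors = FALSE, row.names = NULL)
  list(F = an[["F value"]][1], p = an[["Pr(>F)"]][1], tukey = tukey)
}

#' @export
print.QPCRResult <- function(x, ...) {
  cat("delta-delta-Ct analysis of", x$target, "vs",
      paste(x$references, collapse = "+"),
      "(control:", paste0(x$control, ")\n"))
  print(x$groups, digits = 4)
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.4g\n",
              x$anova$F, x$anova$p))
  invisible(x)
}
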