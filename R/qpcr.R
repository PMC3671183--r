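# Relative quantification from Ct tables and one-way ANOVA with Tukey HSD.

#' Read / write a Ct table as CSV
#'
#' Columns: `sample_id`, `group`, `gene`, `technical_replicate`, `ct`.
#'
#' @param path CSV file.
#' @param reference_gene the internal reference gene (e.g. "Gapdh").
#' @return a `ct_table` data.frame (read) or `path` invisibly (write).
#' @export
read_ct_table <- function(path, reference_gene = "Gapdh") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "group", "gene", "ct")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("Ct table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (is.null(df$technical_replicate)) df$technical_replicate <- 1L
  structure(df, reference_gene = reference_gene,
            class = c("ct_table", "data.frame"))
}

#' @rdname read_ct_table
#' @param table a `ct_table`.
#' @export
write_ct_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Per-sample delta-Ct values against the reference gene
#'
#' Technical replicates of each (sample, gene) are collapsed by arithmetic
#' mean of Ct before differencing.
#' @noRd
delta_ct_per_sample <- function(table, reference_gene) {
  df <- as.data.frame(table)
  if (any(!is.finite(df$ct))) stop("non-finite Ct values", call. = FALSE)
  agg <- stats::aggregate(ct ~ sample_id + group + gene, data = df, FUN = mean)
  ref <- agg[agg$gene == reference_gene, c("sample_id", "ct")]
  names(ref)[2] <- "ct_ref"
  samples_missing <- setdiff(unique(agg$sample_id), ref$sample_id)
  if (length(samples_missing)) {
    stop("reference gene '", reference_gene, "' missing for sample(s): ",
         paste(samples_missing, collapse = ", "), call. = FALSE)
  }
  m <- merge(agg, ref, by = "sample_id")
  m$delta_ct <- m$ct - m$ct_ref
  m
}

#' Relative expression by the 2^-dCt or 2^-ddCt method
#'
#' In `delta_ct` mode each sample's fold is `2^-(Ct(gene) - Ct(reference))`
#' and folds are averaged across biological samples (mean and SEM), per gene
#' and group; the reference gene's fold is identically 1. In
#' `delta_delta_ct` mode each sample's delta-Ct is further referenced to the
#' mean delta-Ct of the calibrator group for that gene before the `2^-x`
#' transform, so the calibrator group centers at fold 1.
#'
#' @param table a `ct_table` (see [generate_ct_table()] / [read_ct_table()]).
#' @param reference_gene internal reference; defaults to the table attribute.
#' @param mode `"delta_ct"` or `"delta_delta_ct"`.
#' @param calibrator_group required for `delta_delta_ct`.
#' @return data.frame of class `relative_expression` with columns `gene`,
#'   `group`, `mode`, `fold`, `sem_fold`, `n`.
#' @export
relative_expression <- function(table,
                                reference_gene = attr(table, "reference_gene"),
                                mode = c("delta_ct", "delta_delta_ct"),
                                calibrator_group = NULL) {
  mode <- match.arg(mode)
  if (is.null(reference_gene)) stop("reference_gene must be given", call. = FALSE)
  m <- delta_ct_per_sample(table, reference_gene)
  if (mode == "delta_delta_ct") {
    if (is.null(calibrator_group)) {
      stop("delta_delta_ct mode requires a calibrator_group", call. = FALSE)
    }
    cal <- m[m$group == calibrator_group, ]
    if (nrow(cal) == 0L) stop("empty calibrator group '", calibrator_group, "'",
                              call. = FALSE)
    cal_mean <- tapply(cal$delta_ct, cal$gene, mean)
    m <- m[m$gene %in% names(cal_mean), ]
    m$fold_sample <- 2^-(m$delta_ct - cal_mean[m$gene])
  } else {
    m$fold_sample <- 2^-m$delta_ct
  }
  out <- do.call(rbind, lapply(split(m, list(m$gene, m$group), drop = TRUE),
                               function(d) {
    n <- nrow(d)
    data.frame(gene = d$gene[1], group = d$group[1], mode = mode,
               fold = mean(d$fold_sample),
               sem_fold = if (n > 1) stats::sd(d$fold_sample) / sqrt(n) else 0,
               n = n, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  class(out) <- c("relative_expression", "data.frame")
  out
}

#' One-way ANOVA with Tukey's HSD post-hoc procedure
#'
#' Standard one-way decomposition `F = MS_between / MS_within` with
#' `df_between = k - 1`, `df_within = N - k`, followed by all pairwise Tukey
#' comparisons: `q = |mean_i - mean_j| / sqrt(MS_within/2 * (1/n_i + 1/n_j))`
#' with the adjusted p-value from the studentized range distribution with
#' parameters (k, df_within). Equal within-group variance is assumed, not
#' enforced. If within-group variance is exactly zero while means differ, F
#' is infinite and is reported with `p_value = 0` and `degenerate = TRUE`.
#'
#' @param values numeric observations.
#' @param groups group labels (same length; >= 2 groups, each with >= 2
#'   observations).
#' @return object of class `anova_result`: `F`, `df_between`, `df_within`,
#'   `p_value`, `degenerate`, and data.frame `tukey` (group_i, group_j,
#'   mean_diff, q_statistic, adjusted_p).
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (length(values) != length(groups)) stop("length mismatch", call. = FALSE)
  n_i <- table(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups", call. = FALSE)
  if (any(n_i < 2L)) stop("every group needs at least 2 observations",
                          call. = FALSE)
  k <- nlevels(groups)
  N <- length(values)
  means <- tapply(values, groups, mean)
  df_b <- k - 1L
  df_w <- N - k

  # degeneracy is judged on the data itself: aov reports a tiny nonzero
  # residual mean square for a perfect fit, with an unreliable huge F
  ssw_exact <- sum((values - means[groups])^2)
  ssb_exact <- sum(n_i * (means - mean(values))^2)
  degenerate <- ssw_exact == 0 && ssb_exact > 0

  fit <- stats::aov(values ~ groups, data = data.frame(values = values,
                                                       groups = groups))
  tab <- suppressWarnings(stats::anova(fit))
  ms_b <- tab[["Mean Sq"]][1]
  ms_w <- tab[["Mean Sq"]][2]
  F_stat <- if (degenerate) Inf else if (ms_b <= 0) 0 else tab[["F value"]][1]
  p <- if (degenerate) 0 else if (F_stat == 0) 1 else tab[["Pr(>F)"]][1]
  if (degenerate) ms_w <- 0

  combos <- utils::combn(levels(groups), 2)
  tukey <- do.call(rbind, apply(combos, 2, function(pair) {
    i <- pair[1]; j <- pair[2]
    diff_ij <- means[[i]] - means[[j]]
    se <- sqrt(ms_w / 2 * (1 / n_i[[i]] + 1 / n_i[[j]]))
    q <- if (se == 0) { if (diff_ij == 0) 0 else Inf } else abs(diff_ij) / se
    padj <- if (is.infinite(q)) 0 else
      stats::ptukey(q, nmeans = k, df = df_w, lower.tail = FALSE)
    data.frame(group_i = i, group_j = j, mean_diff = diff_ij,
               q_statistic = q, adjusted_p = padj, stringsAsFactors = FALSE)
  }))
  rownames(tukey) <- NULL
  structure(list(F = F_stat, df_between = df_b, df_within = df_w,
                 p_value = p, degenerate = degenerate, tukey = tukey),
            class = "anova_result")
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("<anova_result> F(%d, %d) = %.4g, p = %.4g%s\n",
              x$df_between, x$df_within, x$F, x$p_value,
              if (x$degenerate) " [degenerate: zero within-group variance]" else ""))
  print(x$tukey)
  invisible(x)
}
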