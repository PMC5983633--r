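## TPM normalisation, negative-binomial differential expression with the
## |log2FC| >= 1 and adjusted-p <= 0.05 decision rule, comparison summaries
## (up/down tallies and Venn regions) and the 2^-ddCt qPCR calculation.

#' Transcripts per million (TPM)
#'
#' `TPM = count / total_clean x 1e6`, normalising miRNA read counts to the
#' total number of clean reads of the library.
#'
#' @param count miRNA read count(s).
#' @param total_clean total clean reads of the library (> 0).
#' @return TPM value(s).
#' @export
tpm <- function(count, total_clean) {
  if (any(total_clean <= 0)) stop("total_clean must be positive")
  count / total_clean * 1e6
}

#' Assemble a count matrix with library metadata
#'
#' @param counts integer matrix, miRNAs x libraries (dimnames required).
#' @param samples data.frame with columns `library_id`, `tissue`,
#'   `treatment`, `replicate`, `total_clean_reads`; one row per column of
#'   `counts`.
#' @return object of class `count_matrix` (list with `counts`, `samples`).
#' @export
count_matrix <- function(counts, samples) {
  stopifnot(is.matrix(counts), !is.null(rownames(counts)),
            !is.null(colnames(counts)),
            all(c("library_id", "tissue", "treatment", "replicate",
                  "total_clean_reads") %in% names(samples)),
            nrow(samples) == ncol(counts))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  samples <- samples[match(colnames(counts), samples$library_id), ]
  if (any(is.na(samples$library_id))) stop("sample sheet missing a library")
  if (any(colSums(counts) > samples$total_clean_reads)) {
    stop("column sum exceeds total_clean_reads")
  }
  structure(list(counts = counts, samples = samples), class = "count_matrix")
}

#' TPM matrix of a count matrix
#'
#' @param cm a [count_matrix()].
#' @return numeric matrix of TPM values.
#' @export
tpm_matrix <- function(cm) {
  stopifnot(inherits(cm, "count_matrix"))
  sweep(cm$counts, 2L, cm$samples$total_clean_reads, "/") * 1e6
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up BH with monotonicity enforcement, returned in input order.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Negative-binomial Wald test for differential expression
#'
#' Per miRNA: `log2FC = log2((mean TPM_B + c) / (mean TPM_A + c))` with
#' pseudocount `c`; the Wald statistic uses a negative-binomial variance
#' with a method-of-moments dispersion pooled across both groups (floored at
#' 1e-8) and is referred to a t distribution with `nA + nB - 2` df; p-values
#' are BH-adjusted. Significance is `|log2FC| >= lfc_threshold` and
#' `padj <= alpha`. miRNAs with zero counts in every library of both groups
#' are dropped.
#'
#' @param cm a [count_matrix()].
#' @param group_a,group_b disjoint character vectors of library ids, each of
#'   size >= 2. `group_a` is the reference (e.g. control): positive log2FC
#'   means higher in `group_b`.
#' @param comparison label for the output (default `"B vs A"` built from the
#'   group names).
#' @param pseudocount pseudocount `c` in TPM units (default 1).
#' @param lfc_threshold,alpha the significance rule (defaults 1 and 0.05).
#' @param prior_df weight (in pseudo-samples) of the across-miRNA median
#'   dispersion when moderating the noisy per-miRNA moment estimate
#'   (default 10; 0 disables moderation).
#' @return data.frame with columns `mirna_id`, `comparison`, `baseMeanA`,
#'   `baseMeanB` (mean TPM), `log2FC`, `p`, `padj`, `significant`,
#'   `direction`.
#' @export
de_test <- function(cm, group_a, group_b, comparison = NULL,
                    pseudocount = 1, lfc_threshold = 1, alpha = 0.05,
                    prior_df = 10) {
  stopifnot(inherits(cm, "count_matrix"))
  if (length(intersect(group_a, group_b))) stop("groups overlap")
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 libraries")
  }
  libs <- cm$samples$library_id
  if (!all(c(group_a, group_b) %in% libs)) stop("unknown library id")
  if (is.null(comparison)) {
    comparison <- paste(paste(group_b, collapse = "/"), "vs",
                        paste(group_a, collapse = "/"))
  }
  y <- cm$counts[, c(group_a, group_b), drop = FALSE]
  keep <- rowSums(y) > 0
  y <- y[keep, , drop = FALSE]
  s <- cm$samples$total_clean_reads[match(colnames(y), libs)] / 1e6
  ia <- seq_along(group_a)
  ib <- length(group_a) + seq_along(group_b)
  tpm_y <- sweep(y, 2L, s, "/")
  mu_a <- rowMeans(tpm_y[, ia, drop = FALSE])
  mu_b <- rowMeans(tpm_y[, ib, drop = FALSE])
  ## method-of-moments dispersion, pooled over both groups
  mu_fit <- cbind(matrix(mu_a, nrow(y), length(ia)),
                  matrix(mu_b, nrow(y), length(ib)))
  m <- sweep(mu_fit, 2L, s, "*")             # fitted counts
  term <- ((y - m)^2 - m) / m^2
  term[!is.finite(term)] <- NA
  n_term <- rowSums(is.finite(term))
  phi_raw <- rowMeans(term, na.rm = TRUE)
  phi_raw[!is.finite(phi_raw)] <- 0
  phi_raw <- pmax(phi_raw, 0)
  ## moderate the per-miRNA moment estimate toward the across-miRNA median
  ## (with 3 replicates per group the raw estimator is very noisy)
  phi_bar <- median(phi_raw)
  phi <- pmax((n_term * phi_raw + prior_df * phi_bar) /
                pmax(n_term + prior_df, 1), 1e-8)
  var_mu <- function(mu, idx) {
    rowSums(outer(mu, 1 / s[idx]) + phi * mu^2) / length(idx)^2
  }
  va <- var_mu(mu_a, ia)
  vb <- var_mu(mu_b, ib)
  lfc <- log2((mu_b + pseudocount) / (mu_a + pseudocount))
  se <- sqrt(va / (mu_a + pseudocount)^2 + vb / (mu_b + pseudocount)^2) / log(2)
  stat <- ifelse(se > 0, lfc / se, 0)
  df <- length(ia) + length(ib) - 2L
  p <- 2 * pt(-abs(stat), df = df)
  p[se == 0] <- 1
  padj <- bh_adjust(p)
  sig <- abs(lfc) >= lfc_threshold & padj <= alpha
  data.frame(mirna_id = rownames(y), comparison = comparison,
             baseMeanA = mu_a, baseMeanB = mu_b, log2FC = lfc,
             p = p, padj = padj, significant = sig,
             direction = ifelse(lfc >= 0, "up", "down"),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Summarise differential-expression comparisons
#'
#' Per-comparison up/down tallies of significant miRNAs and all Venn
#' regions of the significant sets for up to three comparisons.
#'
#' @param de_results list of data.frames from [de_test()] (named or using
#'   their `comparison` column).
#' @return list with `per_comparison` (data.frame: comparison, n_significant,
#'   up, down) and `venn` (data.frame: region, count) for `k <= 3`
#'   comparisons (`NULL` above).
#' @export
comparison_summary <- function(de_results) {
  if (is.null(names(de_results))) {
    names(de_results) <- vapply(de_results,
                                function(d) d$comparison[1L], character(1))
  }
  per <- do.call(rbind, lapply(names(de_results), function(nm) {
    d <- de_results[[nm]]
    sig <- d[d$significant, , drop = FALSE]
    data.frame(comparison = nm, n_significant = nrow(sig),
               up = sum(sig$direction == "up"),
               down = sum(sig$direction == "down"))
  }))
  venn <- NULL
  k <- length(de_results)
  if (k >= 1L && k <= 3L) {
    sets <- lapply(de_results, function(d) d$mirna_id[d$significant])
    universe <- unique(unlist(sets))
    member <- vapply(sets, function(s) universe %in% s,
                     logical(length(universe)))
    if (length(universe) == 1L) member <- matrix(member, nrow = 1L)
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    combos <- combos[rowSums(combos) > 0L, , drop = FALSE]
    venn <- do.call(rbind, lapply(seq_len(nrow(combos)), function(r) {
      inc <- as.logical(combos[r, ])
      cnt <- if (length(universe)) {
        sum(apply(member, 1L, function(m) all(m == inc)))
      } else 0L
      data.frame(region = paste(names(de_results)[inc], collapse = " & "),
                 count = cnt)
    }))
  }
  list(per_comparison = per, venn = venn)
}

#' Relative expression by the 2^-ddCt method
#'
#' `2^-[(Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)]`.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   cycle-threshold values (all required, positive).
#' @return relative expression of the target in treated vs control.
#' @export
#' @examples
#' ddct(20, 15, 18, 15)  # ddCt = 2 -> 0.25
ddct <- function(ct_target_treated, ct_ref_treated,
                 ct_target_control, ct_ref_control) {
  cts <- c(ct_target_treated, ct_ref_treated,
           ct_target_control, ct_ref_control)
  if (any(is.na(cts))) stop("missing Ct value")
  if (any(cts <= 0)) stop("Ct values must be positive")
  dd <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-dd)
}
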