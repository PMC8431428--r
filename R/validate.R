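# qPCR relative quantification (2^-ddCt, Livak) and RNA-seq concordance.

#' Relative expression by the 2^-ddCt method
#'
#' Per sample (genotype x replicate), the target gene's CT is normalised by
#' the reference gene: `dCt = CT_target - CT_reference`. Replicates are
#' aggregated at the dCt level (standard Livak practice); the calibrator
#' genotype's mean dCt is subtracted per gene (`ddCt`) and relative
#' expression is `2^-ddCt`, so the calibrator itself is exactly 1.
#' Per-replicate relative expressions (each replicate's dCt against the
#' calibrator mean) provide the reported spread.
#'
#' @param ct data frame with columns `genotype`, `gene`, `replicate`, `ct`
#'   (threshold cycles).
#' @param reference_gene internal-control gene (e.g. `"Actin"`); must be
#'   measured in every (genotype, replicate).
#' @param calibrator_genotype genotype whose expression defines 1.
#' @return data frame with one row per (gene, genotype): `dct_mean`, `ddct`,
#'   `rel_expr`, `rel_sd`, `n_reps`.
#' @export
ddct <- function(ct, reference_gene, calibrator_genotype) {
  need <- c("genotype", "gene", "replicate", "ct")
  if (!all(need %in% names(ct))) {
    stop("CT table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(ct$ct))) stop("CT values must be finite")
  if (!reference_gene %in% ct$gene) stop("reference gene '", reference_gene,
                                         "' absent from the CT table")
  if (!calibrator_genotype %in% ct$genotype) {
    stop("calibrator genotype '", calibrator_genotype, "' absent from the CT table")
  }
  ref <- ct[ct$gene == reference_gene, ]
  ref_key <- paste(ref$genotype, ref$replicate)
  ref_ct <- tapply(ref$ct, ref_key, mean)

  targ <- ct[ct$gene != reference_gene, ]
  key <- paste(targ$genotype, targ$replicate)
  missing_ref <- unique(key[!key %in% names(ref_ct)])
  if (length(missing_ref)) {
    stop("reference gene missing for sample(s): ",
         paste(missing_ref, collapse = "; "))
  }
  targ$dct <- targ$ct - as.numeric(ref_ct[key])

  combos <- unique(targ[, c("gene", "genotype")])
  calib_mean <- function(g) {
    v <- targ$dct[targ$gene == g & targ$genotype == calibrator_genotype]
    if (!length(v)) stop("calibrator genotype has no measurements for gene '", g, "'")
    mean(v)
  }
  out <- do.call(rbind, lapply(seq_len(nrow(combos)), function(i) {
    g <- combos$gene[i]; geno <- combos$genotype[i]
    v <- targ$dct[targ$gene == g & targ$genotype == geno]
    cal <- calib_mean(g)
    rel_reps <- 2^-(v - cal)
    data.frame(gene = g, genotype = geno, dct_mean = mean(v),
               ddct = mean(v) - cal, rel_expr = 2^-(mean(v) - cal),
               rel_sd = if (length(v) > 1) stats::sd(rel_reps) else NA_real_,
               n_reps = length(v), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Direction concordance and rank correlation of qPCR vs RNA-seq
#'
#' Merges the two measurement tables on (gene, genotype), requires at least
#' three shared points, and reports (i) the fraction of within-gene genotype
#' contrasts whose direction agrees between the platforms (ties agree only
#' with ties) and (ii) the Spearman rank correlation across all shared
#' points.
#'
#' @param qpcr data frame with columns `gene`, `genotype`, `value`
#'   (e.g. `rel_expr` from [ddct()]).
#' @param rnaseq data frame with the same columns holding normalised
#'   expression (or fold changes) per genotype.
#' @return list with `concordance` (fraction in \[0, 1\]), `spearman`, and
#'   `n_points`.
#' @export
concordance <- function(qpcr, rnaseq) {
  need <- c("gene", "genotype", "value")
  if (!all(need %in% names(qpcr)) || !all(need %in% names(rnaseq))) {
    stop("both tables need columns gene, genotype, value")
  }
  m <- merge(qpcr[, need], rnaseq[, need], by = c("gene", "genotype"),
             suffixes = c("_qpcr", "_rnaseq"))
  if (nrow(m) < 3) stop("fewer than 3 shared (gene, genotype) points")
  agree <- 0L; total <- 0L
  for (g in unique(m$gene)) {
    sub <- m[m$gene == g, ]
    if (nrow(sub) < 2) next
    idx <- utils::combn(nrow(sub), 2)
    for (c_i in seq_len(ncol(idx))) {
      i <- idx[1, c_i]; j <- idx[2, c_i]
      dq <- sign(sub$value_qpcr[i] - sub$value_qpcr[j])
      dr <- sign(sub$value_rnaseq[i] - sub$value_rnaseq[j])
      total <- total + 1L
      if (dq == dr) agree <- agree + 1L
    }
  }
  rho <- stats::cor(m$value_qpcr, m$value_rnaseq, method = "spearman")
  list(concordance = if (total) agree / total else NA_real_,
       spearman = unname(rho), n_points = nrow(m))
}
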