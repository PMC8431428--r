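# End-to-end orchestration: DE on the three pairwise comparisons of each
# triad and time point, twelve-class pattern assignment, category summaries,
# Venn counts, optional heterosis and enrichment, and a reproducibility
# manifest. All outputs are plain TSV/JSON and byte-stable under a fixed
# input bundle.

.triads_from_design <- function(design) {
  out <- list()
  for (tid in unique(design$triad_id)) {
    d <- design[design$triad_id == tid, ]
    pick <- function(role) {
      g <- unique(d$genotype[d$role == role])
      if (length(g) != 1) {
        stop("triad '", tid, "' must have exactly one ", role,
             " genotype, found: ", length(g))
      }
      g
    }
    out[[tid]] <- c(female = pick("female_parent"), male = pick("male_parent"),
                    hybrid = pick("hybrid"))
  }
  out
}

#' Run the full triad analysis pipeline
#'
#' For every triad and time point in the design: tests the three pairwise
#' comparisons (female vs male, female vs hybrid, male vs hybrid; log2 fold
#' changes are always second-over-first, so hybrid comparisons read "up =
#' higher in the hybrid"), applies the DEG rule, classifies the DEG universe
#' into the twelve inheritance-mode classes, tallies classes and categories,
#' and counts the Venn regions of the two hybrid-parent DEG sets. When a
#' phenotype table is supplied, mid-/high-parent heterosis is computed per
#' triad; when an annotation map is supplied, the up- and down-overdominant
#' gene sets are tested for term over-representation against all genes.
#' Every table is written under `out_dir` together with a `manifest.json`
#' recording package version, thresholds and output checksums.
#'
#' @param counts genes x samples count matrix (or a counts TSV path).
#' @param design sample sheet data frame (or CSV path); see
#'   [read_sample_sheet()] for the columns.
#' @param out_dir output directory, created if needed.
#' @param pheno optional phenotype data frame (or CSV path).
#' @param annotation optional annotation map (named list, or two-column TSV
#'   path).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param lfc DEG |log2fc| threshold (default 1).
#' @param lfc_relation |log2fc| threshold for the classifier's relations
#'   (default 0, see [classify_triad()]).
#' @param time_points time points to analyse (default: all in the design).
#' @param dispersion_fit `"trended"` (default; genewise method-of-moments
#'   dispersions smoothed along the mean, see [dispersion_trend()]) or
#'   `"genewise"`.
#' @return invisibly, a nested list of all result objects plus the manifest.
#' @export
run_pipeline <- function(counts, design, out_dir, pheno = NULL,
                         annotation = NULL, alpha = 0.05, lfc = 1,
                         lfc_relation = 0, time_points = NULL,
                         dispersion_fit = c("trended", "genewise")) {
  dispersion_fit <- match.arg(dispersion_fit)
  if (is.character(counts)) counts <- read_counts(counts)
  if (is.character(design)) design <- read_sample_sheet(design)
  if (is.character(pheno)) pheno <- read_phenotypes(pheno)
  if (is.character(annotation)) annotation <- read_annotation_tsv(annotation)
  if (alpha <= 0 || lfc < 0) stop("thresholds must be positive")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (is.null(time_points)) time_points <- unique(design$time_point)
  triads <- .triads_from_design(design)
  size_factors <- estimate_size_factors(counts)
  results <- list()

  for (tid in names(triads)) {
    tri <- triads[[tid]]
    # gene dispersion pooled over all cells of the triad (both time points)
    # and smoothed along the mean: genewise estimates at 2-3 replicates are
    # too noisy to plug into the Wald statistic directly
    disp_gene <- estimate_dispersion(counts, design,
                                     size_factors = size_factors,
                                     groups = unname(tri))
    disp <- if (dispersion_fit == "trended") {
      dispersion_trend(disp_gene,
                       rowMeans(normalized_counts(counts, size_factors)))
    } else {
      disp_gene
    }
    for (tp in time_points) {
      message("[triadex] DE + classification: triad ", tid, ", time point ", tp)
      de_fm <- nb_wald_test(counts, design, tri[["female"]], tri[["male"]],
                            time_point = tp, size_factors = size_factors,
                            dispersion = disp)
      de_fh <- nb_wald_test(counts, design, tri[["female"]], tri[["hybrid"]],
                            time_point = tp, size_factors = size_factors,
                            dispersion = disp)
      de_mh <- nb_wald_test(counts, design, tri[["male"]], tri[["hybrid"]],
                            time_point = tp, size_factors = size_factors,
                            dispersion = disp)
      tag <- paste0(tid, "_", tp)
      for (de in list(de_fm, de_fh, de_mh)) {
        cmp <- gsub(" ", "_", attr(de, "comparison"))
        write_tsv(call_degs(de, alpha, lfc),
                  file.path(out_dir, paste0("de_", tag, "_", cmp, ".tsv")))
      }
      assignment <- classify_triad(de_fm, de_fh, de_mh, alpha = alpha,
                                   lfc = lfc, lfc_relation = lfc_relation)
      write_tsv(assignment, file.path(out_dir, paste0("patterns_", tag, ".tsv")))
      summ <- pattern_summary(assignment)
      write_tsv(summ$category_counts,
                file.path(out_dir, paste0("categories_", tag, ".tsv")))

      deg_set <- function(de) {
        cd <- call_degs(de, alpha, lfc)
        cd$gene_id[cd$call != "ns"]
      }
      venn_sets <- list(deg_set(de_fh), deg_set(de_mh))
      names(venn_sets) <- c(paste0(tri[["female"]], "_vs_", tri[["hybrid"]]),
                            paste0(tri[["male"]], "_vs_", tri[["hybrid"]]))
      venn <- intersect_deg_sets(venn_sets)
      write_tsv(venn, file.path(out_dir, paste0("venn_", tag, ".tsv")))

      enr <- NULL
      if (!is.null(annotation)) {
        bg <- rownames(counts)
        enr <- list()
        for (cat in c("up-overdominant", "down-overdominant")) {
          gs <- assignment$gene_id[assignment$category == cat]
          if (length(gs) == 0) next
          et <- hypergeom_enrich(gs, bg, annotation, alpha = alpha)
          write_tsv(et, file.path(out_dir, paste0("enrich_", tag, "_",
                                                  sub("-overdominant", "_od", cat),
                                                  ".tsv")))
          enr[[cat]] <- et
        }
      }
      results[[tag]] <- list(
        de = list(fm = de_fm, fh = de_fh, mh = de_mh),
        patterns = assignment, summary = summ, venn = venn, enrichment = enr
      )
    }
  }

  het <- NULL
  if (!is.null(pheno)) {
    het <- do.call(rbind, lapply(names(triads), function(tid) {
      h <- compute_heterosis(pheno, triads[[tid]])
      cbind(triad_id = tid, h, stringsAsFactors = FALSE)
    }))
    write_tsv(het, file.path(out_dir, "heterosis.tsv"))
  }

  files <- sort(list.files(out_dir, pattern = "\\.tsv$", full.names = TRUE))
  manifest <- list(
    package = "triadex",
    version = as.character(utils::packageVersion("triadex")),
    thresholds = list(alpha = alpha, lfc = lfc, lfc_relation = lfc_relation),
    time_points = time_points,
    triads = triads,
    n_genes = nrow(counts), n_samples = ncol(counts),
    checksums = as.list(stats::setNames(unname(tools::md5sum(files)),
                                        basename(files)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(list(results = results, heterosis = het, manifest = manifest,
                 size_factors = size_factors))
}
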