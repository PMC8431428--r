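# Plain-text file dialects: counts TSV, sample sheet CSV, phenotype CSV,
# annotation TSV/GMT, CT CSV, DE/pattern result TSVs. Every writer
# round-trips through its reader.

#' Read / write a gene x sample count matrix (TSV)
#'
#' Tab-separated, header row, `gene_id` first column, integer counts.
#' Readers validate uniqueness of identifiers and reject negative or
#' non-integer entries, naming the offending lines.
#'
#' @param path file path.
#' @return `read_counts`: integer matrix with gene rownames and sample
#'   colnames.
#' @export
read_counts <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "gene_id") stop("counts file must start with a gene_id column: ", path)
  if (anyDuplicated(df$gene_id)) stop("duplicate gene ids in ", path)
  if (anyDuplicated(names(df)[-1])) stop("duplicate sample ids in ", path)
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) stop("non-numeric counts in ", path)
  bad <- which(rowSums(m < 0 | m != round(m)) > 0)
  if (length(bad)) {
    stop("negative or non-integer counts in ", path, " at data line(s): ",
         paste(utils::head(bad + 1, 5), collapse = ", "))
  }
  storage.mode(m) <- "integer"
  rownames(m) <- df$gene_id
  m
}

#' @rdname read_counts
#' @param counts genes x samples matrix with dimnames.
#' @export
write_counts <- function(counts, path) {
  df <- data.frame(gene_id = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.read_csv_checked <- function(path, required, what) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " file ", path, " lacks column(s): ", paste(missing, collapse = ", "))
  }
  df
}

#' Read / write a sample sheet (CSV)
#'
#' Columns: `sample_id`, `genotype`, `role`, `triad_id`, `time_point`,
#' `replicate`; `role` must be one of `female_parent`, `male_parent`,
#' `hybrid`.
#'
#' @param path file path.
#' @export
read_sample_sheet <- function(path) {
  df <- .read_csv_checked(path, c("sample_id", "genotype", "role", "triad_id",
                                  "time_point", "replicate"), "sample sheet")
  if (anyDuplicated(df$sample_id)) stop("duplicate sample ids in ", path)
  bad <- !df$role %in% c("female_parent", "male_parent", "hybrid")
  if (any(bad)) stop("invalid role(s) in ", path, ": ",
                     paste(unique(df$role[bad]), collapse = ", "))
  df
}

#' @rdname read_sample_sheet
#' @param design sample sheet data frame.
#' @export
write_sample_sheet <- function(design, path) {
  utils::write.csv(design, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write a phenotype table (CSV)
#'
#' Columns: `genotype`, `trait`, `time_point`, `replicate`, `value`.
#'
#' @param path file path.
#' @export
read_phenotypes <- function(path) {
  .read_csv_checked(path, c("genotype", "trait", "time_point", "replicate",
                            "value"), "phenotype")
}

#' @rdname read_phenotypes
#' @param pheno phenotype data frame.
#' @export
write_phenotypes <- function(pheno, path) {
  utils::write.csv(pheno, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write an annotation map (two-column TSV)
#'
#' Two tab-separated columns `gene_id`, `term_id`, one row per assignment.
#'
#' @param path file path.
#' @return `read_annotation_tsv`: named list term -> gene ids.
#' @export
read_annotation_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "term_id") %in% names(df))) {
    stop("annotation file ", path, " must have columns gene_id, term_id")
  }
  split(df$gene_id, df$term_id)
}

#' @rdname read_annotation_tsv
#' @param annotation named list term -> gene ids.
#' @export
write_annotation_tsv <- function(annotation, path) {
  df <- data.frame(
    gene_id = unlist(annotation, use.names = FALSE),
    term_id = rep(names(annotation), lengths(annotation)),
    stringsAsFactors = FALSE
  )
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write an annotation map (GMT)
#'
#' GMT lines are `term <TAB> description <TAB> gene1 <TAB> gene2 ...`.
#' Terms with fewer than `min_term` genes are dropped with a warning.
#'
#' @param path file path.
#' @param min_term minimum genes per kept term (default 1 keeps everything).
#' @return `read_gmt`: named list term -> gene ids.
#' @export
read_gmt <- function(path, min_term = 1) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  short <- lengths(parts) < 3
  anno <- stats::setNames(lapply(parts, function(x) unique(x[-(1:2)])),
                          vapply(parts, `[`, "", 1))
  anno[short] <- lapply(which(short), function(i) character(0))
  small <- lengths(anno) < min_term
  if (any(small)) {
    warning("dropping ", sum(small), " GMT term(s) with fewer than ",
            min_term, " genes: ", paste(names(anno)[small], collapse = ", "))
    anno <- anno[!small]
  }
  anno
}

#' @rdname read_gmt
#' @param annotation named list term -> gene ids.
#' @param descriptions optional term descriptions (recycled `"NA"`).
#' @export
write_gmt <- function(annotation, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("NA", length(annotation))
  lines <- vapply(seq_along(annotation), function(i) {
    paste(c(names(annotation)[i], descriptions[i], annotation[[i]]),
          collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read / write a qPCR CT table (CSV)
#'
#' Columns: `genotype`, `gene`, `replicate`, `ct`.
#'
#' @param path file path.
#' @export
read_ct <- function(path) {
  .read_csv_checked(path, c("genotype", "gene", "replicate", "ct"), "CT")
}

#' @rdname read_ct
#' @param ct CT data frame.
#' @export
write_ct <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a generic result table (TSV)
#'
#' @param df data frame.
#' @param path file path.
#' @export
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulated bundle to a directory
#'
#' @param sim result of [simulate_triad_counts()].
#' @param dir output directory (created if needed).
#' @return invisibly, the written file paths.
#' @export
write_sim_bundle <- function(sim, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    counts = write_counts(sim$counts, file.path(dir, "counts.tsv")),
    design = write_sample_sheet(sim$design, file.path(dir, "samples.csv")),
    truth = write_tsv(sim$truth, file.path(dir, "truth.tsv"))
  )
  invisible(paths)
}
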