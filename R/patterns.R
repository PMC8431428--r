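# Twelve-class inheritance-mode classification of triad expression.
#
# Relations are encoded as "gt", "lt", "eq" and always read left-to-right:
#   fm = female parent vs male parent  ("gt" means F > M)
#   hf = hybrid vs female parent       ("gt" means H > F)
#   hm = hybrid vs male parent         ("gt" means H > M)

.relation_levels <- c("gt", "lt", "eq")

.rule_table <- data.frame(
  fm    = c("gt", "lt", "gt", "lt", "lt", "gt", "eq", "gt", "lt", "eq", "gt", "lt"),
  hf    = c("lt", "gt", "eq", "eq", "gt", "lt", "lt", "lt", "lt", "gt", "gt", "gt"),
  hm    = c("gt", "lt", "gt", "lt", "eq", "eq", "lt", "lt", "lt", "gt", "gt", "gt"),
  class = as.character(1:12),
  stringsAsFactors = FALSE
)

.class_levels <- c(as.character(1:12), "conserved", "unclassified")

.class_category <- c(
  "1" = "additive", "2" = "additive",
  "3" = "ELD-F", "4" = "ELD-F",
  "5" = "ELD-M", "6" = "ELD-M",
  "7" = "down-overdominant", "8" = "down-overdominant", "9" = "down-overdominant",
  "10" = "up-overdominant", "11" = "up-overdominant", "12" = "up-overdominant",
  "conserved" = "conserved", "unclassified" = "unclassified"
)

.swap_map <- c(
  "1" = "2", "2" = "1", "3" = "5", "5" = "3", "4" = "6", "6" = "4",
  "7" = "7", "8" = "9", "9" = "8", "10" = "10", "11" = "12", "12" = "11",
  "conserved" = "conserved", "unclassified" = "unclassified"
)

#' Classify call triples into the twelve inheritance-mode classes
#'
#' Maps the three pairwise relations of a triad (female parent F, male parent
#' M, hybrid H) onto one of twelve inheritance-mode classes, `"conserved"`
#' (no difference anywhere), or `"unclassified"` (an internally inconsistent
#' triple such as H equal to one parent yet below the other while the parents
#' do not differ).
#'
#' The class layout follows the standard scheme for allopolyploid / hybrid
#' expression studies: classes 1-2 are additive (hybrid strictly intermediate),
#' 3-4 expression-level dominance towards the female parent (ELD-F), 5-6
#' ELD towards the male parent (ELD-M), 7-9 down-overdominant (hybrid below
#' both parents) and 10-12 up-overdominant (hybrid above both parents).
#' Within a category the sub-pattern index is an internal convention with the
#' parents-equal sub-pattern placed first (classes 7 and 10).
#'
#' @param c_fm relation of female vs male parent; one of `"gt"` (F > M),
#'   `"lt"` (F < M), `"eq"` (no significant difference). Vectorised.
#' @param c_hf relation of hybrid vs female parent (`"gt"` = H > F).
#' @param c_hm relation of hybrid vs male parent (`"gt"` = H > M).
#' @return character vector of class labels in
#'   `c(as.character(1:12), "conserved", "unclassified")`.
#' @seealso [pattern_category()], [classify_triad()], [swap_parents()]
#' @examples
#' classify_gene("gt", "lt", "gt")  # additive, female-high -> "1"
#' classify_gene("eq", "gt", "gt")  # up-overdominant, parents equal -> "10"
#' @export
classify_gene <- function(c_fm, c_hf, c_hm) {
  n <- max(length(c_fm), length(c_hf), length(c_hm))
  c_fm <- rep_len(as.character(c_fm), n)
  c_hf <- rep_len(as.character(c_hf), n)
  c_hm <- rep_len(as.character(c_hm), n)
  bad <- !(c_fm %in% .relation_levels) | !(c_hf %in% .relation_levels) |
    !(c_hm %in% .relation_levels)
  if (any(bad)) {
    stop("relations must be one of 'gt', 'lt', 'eq'; offending values: ",
         paste(unique(c(c_fm[bad], c_hf[bad], c_hm[bad])), collapse = ", "))
  }
  key <- paste(c_fm, c_hf, c_hm)
  rule_key <- paste(.rule_table$fm, .rule_table$hf, .rule_table$hm)
  cls <- .rule_table$class[match(key, rule_key)]
  cls[is.na(cls) & key == "eq eq eq"] <- "conserved"
  cls[is.na(cls)] <- "unclassified"
  cls
}

#' Category of an inheritance-mode class
#'
#' @param class character vector of class labels as returned by
#'   [classify_gene()].
#' @return character vector with values in `additive`, `ELD-F`, `ELD-M`,
#'   `down-overdominant`, `up-overdominant`, `conserved`, `unclassified`.
#' @export
pattern_category <- function(class) {
  class <- as.character(class)
  bad <- !(class %in% .class_levels)
  if (any(bad)) stop("unknown class label(s): ", paste(unique(class[bad]), collapse = ", "))
  unname(.class_category[class])
}

#' Three-valued relation calls from a pairwise DE table
#'
#' Converts a [nb_wald_test()] result for a comparison "A vs B"
#' (log2fc = log2(B/A)) into left-vs-right relations `"gt"`/`"lt"`/`"eq"`
#' for the *first-named* group, i.e. a significant positive log2fc (B higher)
#' yields `"lt"` for A vs B.
#'
#' @param de DE table (data frame with `log2fc`, `p_adj`).
#' @param alpha adjusted-p significance threshold.
#' @param lfc minimum |log2fc| for a relation to count as a difference;
#'   the classifier defaults to 0 (significance-only relations) because a
#'   fold-change gate makes strict intermediacy (additive classes)
#'   undetectable whenever the parental gap is below twice the gate.
#' @return character vector of relations, one per gene.
#' @export
de_relation <- function(de, alpha = 0.05, lfc = 0) {
  sig <- !is.na(de$p_adj) & de$p_adj < alpha & abs(de$log2fc) >= lfc & de$log2fc != 0
  rel <- rep("eq", nrow(de))
  rel[sig & de$log2fc > 0] <- "lt"   # second group higher => first group lower
  rel[sig & de$log2fc < 0] <- "gt"
  rel
}

#' Classify every gene of a triad from three pairwise DE tables
#'
#' Builds the DEG universe (genes called up or down in at least one of the
#' three pairwise comparisons under the `alpha`/`lfc` DEG rule), derives the
#' three relations per gene, and assigns each universe gene a class and
#' category. Genes outside the universe are reported as `"conserved"`.
#'
#' @param de_fm DE table for "F vs M" (log2fc = male over female).
#' @param de_fh DE table for "F vs H" (log2fc = hybrid over female).
#' @param de_mh DE table for "M vs H" (log2fc = hybrid over male).
#' @param alpha adjusted-p threshold shared by the DEG rule and the relations.
#' @param lfc |log2fc| threshold of the DEG rule defining the universe
#'   (default 1, the conventional two-fold cut-off).
#' @param lfc_relation |log2fc| threshold applied to the three relations fed
#'   to the rule table (default 0; see [de_relation()]).
#' @return data frame with columns `gene_id`, `in_universe`, `rel_fm`,
#'   `rel_hf`, `rel_hm`, `class`, `category`.
#' @export
classify_triad <- function(de_fm, de_fh, de_mh, alpha = 0.05, lfc = 1,
                           lfc_relation = 0) {
  ids <- de_fm$gene_id
  if (is.null(ids)) stop("DE tables must carry a gene_id column")
  if (!identical(ids, de_fh$gene_id) || !identical(ids, de_mh$gene_id)) {
    stop("the three DE tables must cover the same genes in the same order")
  }
  deg <- function(de) {
    cl <- call_degs(de, alpha = alpha, lfc = lfc)$call
    cl != "ns"
  }
  in_universe <- deg(de_fm) | deg(de_fh) | deg(de_mh)

  rel_fm <- de_relation(de_fm, alpha, lfc_relation)              # F vs M
  rel_hf <- flip_relation(de_relation(de_fh, alpha, lfc_relation)) # H vs F
  rel_hm <- flip_relation(de_relation(de_mh, alpha, lfc_relation)) # H vs M

  class <- rep("conserved", length(ids))
  class[in_universe] <- classify_gene(rel_fm[in_universe],
                                      rel_hf[in_universe],
                                      rel_hm[in_universe])
  # a universe gene whose relations are all "eq" is inconsistent, not conserved
  class[in_universe & class == "conserved"] <- "unclassified"
  data.frame(
    gene_id = ids, in_universe = in_universe,
    rel_fm = rel_fm, rel_hf = rel_hf, rel_hm = rel_hm,
    class = class, category = pattern_category(class),
    stringsAsFactors = FALSE
  )
}

#' @rdname de_relation
#' @param rel relation vector to invert (swap `"gt"` and `"lt"`).
#' @export
flip_relation <- function(rel) {
  out <- rel
  out[rel == "gt"] <- "lt"
  out[rel == "lt"] <- "gt"
  out
}

#' Relabel classes under a female/male parent swap
#'
#' Swapping the parent labels F and M maps classes 1<->2, 3<->5, 4<->6,
#' 8<->9 and 11<->12 while fixing 7, 10, conserved and unclassified; applying
#' the swap twice is the identity.
#'
#' @param class character vector of class labels.
#' @return relabelled class vector.
#' @export
swap_parents <- function(class) {
  class <- as.character(class)
  bad <- !(class %in% .class_levels)
  if (any(bad)) stop("unknown class label(s): ", paste(unique(class[bad]), collapse = ", "))
  unname(.swap_map[class])
}

#' Per-class and per-category counts of a pattern assignment
#'
#' Conserved genes are tallied separately and excluded from the class counts,
#' mirroring the restriction of the twelve groups to the DEG universe.
#'
#' @param assignment data frame from [classify_triad()].
#' @return list with `class_counts` and `category_counts` data frames and
#'   `n_conserved`.
#' @export
pattern_summary <- function(assignment) {
  u <- assignment[assignment$class != "conserved", , drop = FALSE]
  cls <- factor(u$class, levels = setdiff(.class_levels, "conserved"))
  cat <- factor(u$category,
                levels = setdiff(unique(unname(.class_category)), "conserved"))
  list(
    class_counts = data.frame(class = levels(cls), n = as.integer(table(cls)),
                              stringsAsFactors = FALSE),
    category_counts = data.frame(category = levels(cat), n = as.integer(table(cat)),
                                 stringsAsFactors = FALSE),
    n_conserved = sum(assignment$class == "conserved")
  )
}

#' Venn-region counts for two or three gene sets
#'
#' @param sets named list of 2 or 3 character vectors of gene ids.
#' @return data frame with one row per non-empty-pattern region (exclusive
#'   regions of the Venn partition), columns `region` (set names joined by
#'   `&`, or `<name>_only`) and `n`; the full intersection count is also
#'   available as attribute `"common"`.
#' @examples
#' intersect_deg_sets(list(A = c("a", "b", "c"), B = c("b", "c", "d")))
#' @export
intersect_deg_sets <- function(sets) {
  if (!is.list(sets) || is.null(names(sets)) || any(names(sets) == "") ||
      !(length(sets) %in% 2:3)) {
    stop("sets must be a named list of 2 or 3 gene-id vectors")
  }
  sets <- lapply(sets, unique)
  k <- length(sets)
  universe <- unique(unlist(sets))
  member <- matrix(FALSE, nrow = length(universe), ncol = k,
                   dimnames = list(NULL, names(sets)))
  for (j in seq_len(k)) member[, j] <- universe %in% sets[[j]]
  patt <- if (length(universe)) apply(member, 1, paste, collapse = "") else character(0)
  combos <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), k))[-1, , drop = FALSE])
  region_name <- function(inc) {
    nm <- names(sets)[inc]
    if (length(nm) == 1) paste0(nm, "_only") else paste(nm, collapse = "&")
  }
  out <- data.frame(
    region = apply(combos, 1, region_name),
    n = vapply(seq_len(nrow(combos)), function(i) {
      sum(patt == paste(combos[i, ], collapse = ""))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  attr(out, "common") <- sum(patt == paste(rep(TRUE, k), collapse = ""))
  out
}
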