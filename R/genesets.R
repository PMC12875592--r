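#' Read a pathway annotation export
#'
#' Parses a delimited table of pathway annotations (one row per gene-pathway
#' assignment) as exported from a pathway knowledge base.  Headers are matched
#' case-insensitively; gene symbols are upper-cased and stripped of
#' surrounding whitespace; blank gene rows are dropped.
#'
#' @param path path to a tab- or comma-delimited file with columns
#'   `pathway_id`, `pathway_name`, `gene` (any case).
#' @param source tag naming the annotation source (e.g. `"source_A"`).
#' @param sep field separator; `"\t"` by default.
#' @return data.frame with columns `gene`, `pathway_id`, `pathway_name`,
#'   `source`.
#' @export
load_annotation_table <- function(path, source, sep = "\t") {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "", blank.lines.skip = TRUE)
  if (nrow(tab) == 0L) {
    stop("annotation file is empty: ", path, call. = FALSE)
  }
  wanted <- c("pathway_id", "pathway_name", "gene")
  idx <- match(wanted, tolower(names(tab)))
  if (anyNA(idx)) {
    stop("annotation table is missing required column(s): ",
         paste(wanted[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  out <- tab[, idx]
  names(out) <- wanted
  out$gene <- toupper(trimws(out$gene))
  out <- out[nzchar(out$gene), , drop = FALSE]
  out$source <- source
  key <- paste(out$gene, out$pathway_id, out$source)
  out <- out[!duplicated(key), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene", "pathway_id", "pathway_name", "source")]
}

#' Construct a pathway gene set
#'
#' @param name pathway label (e.g. `"glycolysis"`).
#' @param genes character vector of gene symbols (deduplicated, upper-cased).
#' @param provenance optional data.frame with columns `gene`, `source_A_id`,
#'   `source_B_id` recording the source pathway identifiers per gene.
#' @param exclusions_applied data.frame with columns `gene`, `reason`,
#'   `applied` accumulated by [apply_exclusions()].
#' @return object of class `pathway_geneset`.
#' @export
pathway_geneset <- function(name, genes, provenance = NULL,
                            exclusions_applied = NULL) {
  genes <- sort(unique(toupper(trimws(as.character(genes)))))
  genes <- genes[nzchar(genes)]
  if (is.null(provenance)) {
    provenance <- data.frame(gene = genes,
                             source_A_id = NA_character_,
                             source_B_id = NA_character_,
                             stringsAsFactors = FALSE)
  }
  if (is.null(exclusions_applied)) {
    exclusions_applied <- data.frame(gene = character(), reason = character(),
                                     applied = logical(),
                                     stringsAsFactors = FALSE)
  }
  structure(list(name = name, genes = genes, provenance = provenance,
                 exclusions_applied = exclusions_applied),
            class = "pathway_geneset")
}

#' @export
print.pathway_geneset <- function(x, ...) {
  cat(sprintf("<pathway_geneset> %s: %d genes\n", x$name, length(x$genes)))
  cat("  ", paste(utils::head(x$genes, 12), collapse = ", "),
      if (length(x$genes) > 12) ", ..." else "", "\n", sep = "")
  if (nrow(x$exclusions_applied)) {
    cat(sprintf("  exclusions applied: %d (%d effective)\n",
                nrow(x$exclusions_applied), sum(x$exclusions_applied$applied)))
  }
  invisible(x)
}

#' Consensus gene set from two annotation sources
#'
#' Retains the genes annotated to the pathway in both sources, so that a gene
#' enters the final set only when the two knowledge bases agree.
#'
#' @param name pathway label for the resulting set.
#' @param records_a,records_b annotation data.frames as returned by
#'   [load_annotation_table()], restricted to the same conceptual pathway.
#' @return a [pathway_geneset()].  An empty intersection is valid and returned
#'   with a warning.
#' @export
consensus_gene_set <- function(name, records_a, records_b) {
  ga <- unique(records_a$gene)
  gb <- unique(records_b$gene)
  genes <- sort(intersect(ga, gb))
  if (length(genes) == 0L) {
    warning("consensus gene set '", name, "' is empty: sources share no genes",
            call. = FALSE)
  }
  ia <- match(genes, records_a$gene)
  ib <- match(genes, records_b$gene)
  provenance <- data.frame(
    gene = genes,
    source_A_id = if (length(genes)) records_a$pathway_id[ia] else character(),
    source_B_id = if (length(genes)) records_b$pathway_id[ib] else character(),
    stringsAsFactors = FALSE)
  pathway_geneset(name, genes, provenance)
}

#' Apply a documented exclusion list to a gene set
#'
#' Removes listed genes when present; genes absent from the set are recorded
#' as no-ops so the audit trail is complete.
#'
#' @param gs a [pathway_geneset()].
#' @param exclusions data.frame with columns `gene` and `reason`.
#' @return the gene set with exclusions applied and logged in
#'   `exclusions_applied`.
#' @export
apply_exclusions <- function(gs, exclusions) {
  stopifnot(inherits(gs, "pathway_geneset"))
  if (is.null(exclusions) || nrow(exclusions) == 0L) {
    return(gs)
  }
  stopifnot(all(c("gene", "reason") %in% names(exclusions)))
  excl <- exclusions
  excl$gene <- toupper(trimws(excl$gene))
  applied <- excl$gene %in% gs$genes
  gs$genes <- setdiff(gs$genes, excl$gene)
  gs$provenance <- gs$provenance[gs$provenance$gene %in% gs$genes, ,
                                 drop = FALSE]
  gs$exclusions_applied <- rbind(
    gs$exclusions_applied,
    data.frame(gene = excl$gene, reason = excl$reason, applied = applied,
               stringsAsFactors = FALSE))
  gs
}

#' Genes shared by two pathway gene sets
#'
#' @param gs_a,gs_b finalized [pathway_geneset()] objects.
#' @return character vector of shared gene symbols (sorted); symmetric in its
#'   arguments.
#' @export
pathway_overlap <- function(gs_a, gs_b) {
  stopifnot(inherits(gs_a, "pathway_geneset"), inherits(gs_b, "pathway_geneset"))
  sort(intersect(gs_a$genes, gs_b$genes))
}

#' Default exclusion list
#'
#' The hexokinase isoenzymes gate the entry of glucose into both glycolysis
#' and the pentose phosphate pathway and are therefore excluded from
#' pathway-specific sets.
#'
#' @return data.frame with columns `gene`, `reason`.
#' @export
default_exclusions <- function() {
  path <- system.file("extdata", "genesets", "exclusions.tsv",
                      package = "energymaps")
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Load the packaged energy-pathway gene sets
#'
#' Loads the five consensus energy-metabolism gene sets shipped with the
#' package (glycolysis, pentose phosphate pathway, TCA cycle, oxidative
#' phosphorylation, lactate metabolism and transport).  These fixtures are a
#' synthetic curation: gene membership was assembled from standard pathway
#' knowledge so that the documented structure holds exactly -- the TCA and
#' OXPHOS sets share the three succinate dehydrogenase complex genes active
#' in both pathways, glycolysis and lactate share only the regulatory enzyme
#' gene PFKFB2, hexokinases are excluded, and the OXPHOS set is dominated by
#' nuclear-encoded complex I subunits (mitochondrially encoded genes are
#' absent, as they are from microarray platforms).
#'
#' @param path optional path to a gene-set TSV with columns `pathway`,
#'   `gene`, `source_A_id`, `source_B_id`; defaults to the packaged file.
#' @return named list of [pathway_geneset()] objects.
#' @export
load_energy_genesets <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "genesets", "energy_pathways_synthetic.tsv",
                        package = "energymaps")
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("pathway", "gene") %in% names(tab)))
  out <- lapply(split(tab, tab$pathway), function(d) {
    prov <- data.frame(
      gene = toupper(trimws(d$gene)),
      source_A_id = if ("source_A_id" %in% names(d)) d$source_A_id else NA,
      source_B_id = if ("source_B_id" %in% names(d)) d$source_B_id else NA,
      stringsAsFactors = FALSE)
    prov <- prov[order(prov$gene), , drop = FALSE]
    rownames(prov) <- NULL
    pathway_geneset(d$pathway[1], prov$gene, prov)
  })
  out[unique(tab$pathway)]
}

#' Write a gene set to a TSV file
#'
#' @param gs a [pathway_geneset()] or a named list of them.
#' @param path output path; columns `pathway`, `gene`, `source_A_id`,
#'   `source_B_id`, one row per gene.
#' @return `path`, invisibly.
#' @export
write_geneset_tsv <- function(gs, path) {
  if (inherits(gs, "pathway_geneset")) gs <- list(gs)
  rows <- do.call(rbind, lapply(gs, function(g) {
    data.frame(pathway = g$name, g$provenance, stringsAsFactors = FALSE)
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
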