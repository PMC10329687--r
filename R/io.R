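#' Read a directory of gene trees
#'
#' Reads every \code{*.nwk} file in a directory; gene ids are the file
#' names without extension.
#'
#' @param dir directory of newick files.
#' @return named list of \code{ape::phylo}.
#' @export
read_gene_trees <- function(dir) {
  files <- list.files(dir, pattern = "\\.nwk$", full.names = TRUE)
  .check(length(files) > 0L, paste0("no .nwk files in ", dir))
  trees <- lapply(files, read_newick)
  names(trees) <- sub("\\.nwk$", "", basename(files))
  trees
}

#' Read a directory of gene alignments
#'
#' Reads every \code{*.fasta} file in a directory; gene ids are the file
#' names without extension.
#'
#' @param dir directory of FASTA files.
#' @return named list of \code{codon_aln}.
#' @export
read_gene_alignments <- function(dir) {
  files <- list.files(dir, pattern = "\\.fasta$", full.names = TRUE)
  .check(length(files) > 0L, paste0("no .fasta files in ", dir))
  alns <- lapply(files, read_alignment)
  names(alns) <- sub("\\.fasta$", "", basename(files))
  alns
}

#' Read a gene-annotation table
#'
#' Tab-separated with header columns \code{gene_id} and \code{cc_labels}
#' (semicolon-separated top-level cellular-component terms).
#'
#' @param path TSV path.
#' @return data.frame.
#' @export
read_annotations <- function(path) {
  ann <- utils::read.delim(path, stringsAsFactors = FALSE)
  .check(all(c("gene_id", "cc_labels") %in% names(ann)),
         "annotation table needs columns gene_id, cc_labels")
  ann
}

#' Write a labeled distance matrix as TSV
#'
#' @param D labeled matrix.
#' @param path output path.
#' @export
write_distance_matrix <- function(D, path) {
  utils::write.table(data.frame(tip_id = rownames(D), D,
                                check.names = FALSE),
                     path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
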