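#' Read a GWAS/eQTL summary-statistics table
#'
#' Tab-separated, header row, columns \code{snp, effect_allele, other_allele,
#' eaf, beta, se, pval, n} (eaf and n optional; empty = missing).
#'
#' @param path File path.
#' @return data.frame in the summary-statistics schema.
#' @export
read_summary_stats <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("snp", "effect_allele", "other_allele", "beta", "se", "pval")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L)
    stop(path, ": missing columns: ", paste(missing, collapse = ", "))
  if (!"eaf" %in% names(d)) d$eaf <- NA_real_
  if (!"n" %in% names(d)) d$n <- NA_real_
  d
}

#' Write a summary-statistics table
#' @param d data.frame in the summary-statistics schema.
#' @param path Output file path.
#' @export
write_summary_stats <- function(d, path) {
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a square LD matrix
#'
#' Tab-separated square matrix with snp ids as the header row and first
#' column.
#'
#' @param path File path.
#' @return Numeric matrix with snp-id dimnames.
#' @export
read_ld_matrix <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(d)
  if (nrow(m) != ncol(m)) stop(path, ": LD matrix is not square")
  m
}

#' Write a square LD matrix
#' @param m Matrix with snp-id dimnames.
#' @param path Output file path.
#' @export
write_ld_matrix <- function(m, path) {
  utils::write.table(data.frame(snp = rownames(m), m, check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a per-gene TMR metrics table
#'
#' Tab-separated: \code{gene, cohort, or, pval, pleiotropy_pval,
#' heterogeneity_pval}.
#' @param path File path.
#' @return data.frame.
#' @export
read_gene_metrics <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "cohort", "or", "pval", "pleiotropy_pval")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L)
    stop(path, ": missing columns: ", paste(missing, collapse = ", "))
  d
}

#' Read a per-gene SMR metrics table
#'
#' Tab-separated: \code{gene, cohort, top_snp, b_smr, p_smr, p_heidi}.
#' @param path File path.
#' @return data.frame.
#' @export
read_smr_metrics <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene", "cohort", "b_smr", "p_smr", "p_heidi")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L)
    stop(path, ": missing columns: ", paste(missing, collapse = ", "))
  d
}

#' Load the shipped five-candidate-gene fixture
#'
#' The per-gene two-cohort TMR and SMR metric tables for the five candidate
#' genes (PGAP3, VAMP3, DRAM2, RNASEH2C, PYROXD2) used in the worked example.
#'
#' @return List with \code{tmr} and \code{smr} data.frames.
#' @export
load_candidate_tables <- function() {
  list(
    tmr = read_gene_metrics(system.file("extdata", "table1_tmr.tsv",
                                        package = "excluscope", mustWork = TRUE)),
    smr = read_smr_metrics(system.file("extdata", "table1_smr.tsv",
                                       package = "excluscope", mustWork = TRUE))
  )
}

#' Read a spot table into a spot grid
#'
#' Comma- or tab-separated (sniffed from the header line) with columns
#' \code{spot_id, x, y} followed by per-spot columns: columns containing only
#' 0/1 become labels, all other numeric columns become signals.
#'
#' @param path File path.
#' @return A \code{\link{spot_grid}}.
#' @export
read_spot_table <- function(path) {
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- utils::read.table(path, sep = sep, header = TRUE,
                         stringsAsFactors = FALSE)
  required <- c("spot_id", "x", "y")
  missing <- setdiff(required, names(d))
  if (length(missing) > 0L)
    stop(path, ": missing columns: ", paste(missing, collapse = ", "))
  extra <- setdiff(names(d), required)
  signals <- list()
  labels <- list()
  for (nm in extra) {
    v <- d[[nm]]
    if (!is.numeric(v)) next
    if (all(v %in% c(0, 1))) labels[[nm]] <- as.logical(v)
    else signals[[nm]] <- v
  }
  spot_grid(d$spot_id, d$x, d$y, signals = signals, labels = labels)
}

#' Write a spot grid as a tab-separated spot table
#' @param grid A \code{\link{spot_grid}}.
#' @param path Output file path.
#' @export
write_spot_table <- function(grid, path) {
  d <- data.frame(spot_id = grid$spot_ids, x = grid$coords[, "x"],
                  y = grid$coords[, "y"], stringsAsFactors = FALSE)
  for (nm in names(grid$signals)) d[[nm]] <- grid$signals[[nm]]
  for (nm in names(grid$labels)) d[[nm]] <- as.integer(grid$labels[[nm]])
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Read a sparse count matrix (MatrixMarket + sidecar label files)
#'
#' @param mtx_path MatrixMarket file (genes x cells).
#' @param genes_path,cells_path One name per line.
#' @return A \code{\link{cell_matrix}}.
#' @export
read_cell_matrix <- function(mtx_path, genes_path, cells_path) {
  counts <- Matrix::readMM(mtx_path)
  genes <- readLines(genes_path)
  cells <- readLines(cells_path)
  cell_matrix(counts, genes = genes, cells = cells)
}

#' Write a cell matrix as MatrixMarket plus sidecar label files
#' @param m A \code{\link{cell_matrix}}.
#' @param mtx_path,genes_path,cells_path Output file paths.
#' @export
write_cell_matrix <- function(m, mtx_path, genes_path, cells_path) {
  Matrix::writeMM(m$counts, mtx_path)
  writeLines(m$genes, genes_path)
  writeLines(m$cells, cells_path)
  invisible(NULL)
}

#' Read a bulk expression matrix (tab-separated gene x sample with header)
#'
#' First column = gene names, remaining columns = samples, values on the log2
#' scale.
#' @param path File path.
#' @return A \code{\link{bulk_cohort}}.
#' @export
read_bulk_expression <- function(path) {
  d <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  bulk_cohort(as.matrix(d))
}

#' Write a bulk cohort as a tab-separated expression table
#' @param cohort A \code{\link{bulk_cohort}}.
#' @param path Output file path.
#' @export
write_bulk_expression <- function(cohort, path) {
  utils::write.table(data.frame(gene = cohort$genes, cohort$expression,
                                check.names = FALSE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
}
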