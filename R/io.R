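# Tab-separated matrix and edge-list formats shared by all modules.
# Matrices carry a header row and a first column of gene labels; replicate
# columns are suffixed `_r1`, `_r2`, ... Values are written with 17
# significant digits so write/read round-trips are bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write a labelled matrix as TSV
#'
#' @param m numeric matrix; missing dimnames are filled with `G1..` rows and
#'   `C1..` columns.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path) {
  rn <- rownames(m)
  if (is.null(rn)) rn <- paste0("G", seq_len(nrow(m)))
  cn <- colnames(m)
  if (is.null(cn)) cn <- paste0("C", seq_len(ncol(m)))
  lines <- c(paste(c("", cn), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i)
               paste(c(rn[i], fmt_num(m[i, ])), collapse = "\t"), character(1)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled matrix from TSV
#'
#' Expects the format written by [write_matrix_tsv()]: a header row of column
#' labels and a first column of unique gene labels. Ragged rows, duplicate
#' gene labels and non-numeric cells raise a parse error naming the offending
#' line or label.
#'
#' @param path input file path.
#' @return numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  if (!file.exists(path)) stop_bigsm("parse", "file not found: %s", path)
  lines <- readLines(path)
  if (length(lines) < 2) stop_bigsm("parse", "%s: need a header row and data rows", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]]
  width <- length(header)
  for (k in seq_along(fields)[-1]) {
    if (length(fields[[k]]) != width)
      stop_bigsm("parse", "%s: line %d has %d fields, expected %d",
                 path, k, length(fields[[k]]), width)
  }
  labels <- vapply(fields[-1], `[[`, character(1), 1)
  dup <- labels[duplicated(labels)]
  if (length(dup))
    stop_bigsm("parse", "%s: duplicate gene label '%s'", path, dup[1])
  vals <- matrix(NA_real_, length(labels), width - 1,
                 dimnames = list(labels, header[-1]))
  for (k in seq_along(labels)) {
    raw <- fields[[k + 1]][-1]
    v <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(v) & raw != "NA")
    if (length(bad))
      stop_bigsm("parse", "%s: line %d: non-numeric cell '%s'",
                 path, k + 1, raw[bad[1]])
    vals[k, ] <- v
  }
  vals
}

#' Infer the replicate count from data column names
#'
#' Column names of the form `<gene>_r<k>` mark replicate blocks; the largest
#' k is returned, after checking every base name appears once per replicate.
#' Unsuffixed column names mean a single replicate.
#'
#' @param col_names character vector of column names.
#' @return integer replicate count.
#' @export
infer_replicates <- function(col_names) {
  m <- regmatches(col_names, regexec("^(.*)_r([0-9]+)$", col_names))
  ok <- lengths(m) == 3
  if (!all(ok)) return(1L)
  reps <- as.integer(vapply(m, `[[`, character(1), 3))
  base <- vapply(m, `[[`, character(1), 2)
  r <- max(reps)
  tab <- table(base)
  if (length(unique(tab)) != 1 || unique(tab) != r)
    stop_bigsm("parse", "inconsistent replicate suffixes in column names")
  r
}

#' Read a gold-standard edge list into an adjacency matrix
#'
#' Each line is `regulator<TAB>target<TAB>weight`. Edges run columns to rows:
#' the weight of `G2 -> G1` is stored at row `G1`, column `G2`. Unlisted
#' pairs are zero; an empty file yields the zero matrix.
#'
#' @param path input file path.
#' @param gene_names character vector fixing the matrix dimension and label
#'   order.
#' @return N x N numeric matrix.
#' @export
read_edge_list <- function(path, gene_names) {
  if (!file.exists(path)) stop_bigsm("parse", "file not found: %s", path)
  A <- matrix(0, length(gene_names), length(gene_names),
              dimnames = list(gene_names, gene_names))
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  for (k in seq_along(lines)) {
    f <- strsplit(lines[k], "\t", fixed = TRUE)[[1]]
    if (length(f) != 3)
      stop_bigsm("parse", "%s: line %d has %d fields, expected 3", path, k, length(f))
    if (!(f[1] %in% gene_names))
      stop_bigsm("resolution", "%s: unknown regulator '%s' on line %d", path, f[1], k)
    if (!(f[2] %in% gene_names))
      stop_bigsm("resolution", "%s: unknown target '%s' on line %d", path, f[2], k)
    w <- suppressWarnings(as.numeric(f[3]))
    if (is.na(w))
      stop_bigsm("parse", "%s: line %d: non-numeric weight '%s'", path, k, f[3])
    A[f[2], f[1]] <- w
  }
  A
}

#' Write a network as a gold-standard edge list
#'
#' Nonzero entries are written as `regulator<TAB>target<TAB>weight` lines
#' (columns-to-rows direction), ordered by regulator then target for
#' deterministic output.
#'
#' @param A N x N network matrix with gene-name dimnames.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(A, path) {
  nz <- which(A != 0, arr.ind = TRUE)
  ord <- order(nz[, "col"], nz[, "row"])
  nz <- nz[ord, , drop = FALSE]
  lines <- sprintf("%s\t%s\t%s",
                   colnames(A)[nz[, "col"]], rownames(A)[nz[, "row"]],
                   fmt_num(A[nz]))
  writeLines(lines, path)
  invisible(path)
}

#' Write a simulated benchmark bundle to a directory
#'
#' Emits `network.tsv` (N x N adjacency), `expression.tsv` and
#' `perturbation.tsv` (N x M with replicate-suffixed columns), and
#' `goldstandard.tsv` (edge list).
#'
#' @param sim a `grn_sim` from [simulate_dataset()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_benchmark_bundle <- function(sim, dir) {
  stopifnot(inherits(sim, "grn_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(sim$network, file.path(dir, "network.tsv"))
  write_matrix_tsv(sim$Y, file.path(dir, "expression.tsv"))
  write_matrix_tsv(sim$design, file.path(dir, "perturbation.tsv"))
  write_edge_list(sim$network, file.path(dir, "goldstandard.tsv"))
  invisible(dir)
}

#' Export an inferred posterior to TSV files
#'
#' Writes `posterior_mean.tsv`, `posterior_variance.tsv` and
#' `row_hyperparams.tsv` (gene, noise precision beta, iterations run).
#'
#' @param post a `grn_posterior`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
export_posterior <- function(post, dir) {
  stopifnot(inherits(post, "grn_posterior"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_matrix_tsv(post$mean, file.path(dir, "posterior_mean.tsv"))
  write_matrix_tsv(post$variance, file.path(dir, "posterior_variance.tsv"))
  hp <- data.frame(gene = post$gene_names, beta = fmt_num(post$row_betas),
                   iterations = post$iterations, stringsAsFactors = FALSE)
  utils::write.table(hp, file.path(dir, "row_hyperparams.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}

#' Read a simulation configuration from a YAML file
#'
#' Recognised keys: `n_genes`, `avg_links_per_gene`, `snr`, `replicates`,
#' `seed`, `weight_low`, `weight_high`, `confidence_level`; missing keys take
#' the [sim_config()] defaults.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!file.exists(path)) stop_bigsm("parse", "file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_bigsm("parse", "%s: unknown key '%s'", path, bad[1])
  do.call(sim_config, vals)
}

#' Read a benchmark specification from a YAML file
#'
#' Recognised keys match the arguments of [benchmark_spec()].
#'
#' @param path YAML file path.
#' @return a `benchmark_spec`.
#' @export
read_benchmark_spec <- function(path) {
  if (!file.exists(path)) stop_bigsm("parse", "file not found: %s", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(benchmark_spec))
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop_bigsm("parse", "%s: unknown key '%s'", path, bad[1])
  do.call(benchmark_spec, vals)
}
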