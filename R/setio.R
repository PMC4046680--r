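# I/O and SNP-set construction: genotype matrices, phenotypes, gene
# intervals, GMT pathways, and SNP-to-gene / gene-to-pathway mapping.

#' Construct a genotype matrix object
#'
#' Container for an n samples x d SNPs genotype matrix with entries in
#' \{0, 1, 2\} (minor-allele counts, treated downstream as three unordered
#' categories).
#'
#' @param values integer matrix, n x d, entries 0/1/2.
#' @param snp_ids character vector of d unique SNP identifiers.  Defaults
#'   to column names or `snp1..snpd`.
#' @param sample_ids character vector of n unique sample identifiers.
#' @param snp_positions optional data.frame with columns `chrom` and `pos`
#'   (1-based base-pair position), one row per SNP.
#' @return An object of class `genotype_matrix` with fields `values`,
#'   `snp_ids`, `sample_ids`, `snp_positions`.
#' @export
genotype_matrix <- function(values, snp_ids = NULL, sample_ids = NULL,
                            snp_positions = NULL) {
  values <- as.matrix(values)
  .assert(is.numeric(values), "genotype values must be numeric")
  .assert(!anyNA(values), "genotype matrix contains missing values")
  .assert(all(values %in% c(0, 1, 2)),
          "genotype entries must be 0, 1 or 2; found %s",
          paste(head(setdiff(unique(as.vector(values)), 0:2)), collapse = ", "))
  storage.mode(values) <- "integer"
  n <- nrow(values); d <- ncol(values)
  if (is.null(snp_ids)) snp_ids <- colnames(values)
  if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(d))
  if (is.null(sample_ids)) sample_ids <- rownames(values)
  if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(n))
  .assert(length(snp_ids) == d && !anyDuplicated(snp_ids),
          "snp_ids must be %d unique identifiers", d)
  .assert(length(sample_ids) == n && !anyDuplicated(sample_ids),
          "sample_ids must be %d unique identifiers", n)
  if (!is.null(snp_positions)) {
    .assert(is.data.frame(snp_positions) &&
              all(c("chrom", "pos") %in% names(snp_positions)) &&
              nrow(snp_positions) == d,
            "snp_positions must be a data.frame(chrom, pos) with %d rows", d)
  }
  dimnames(values) <- list(sample_ids, snp_ids)
  structure(list(values = values, snp_ids = as.character(snp_ids),
                 sample_ids = as.character(sample_ids),
                 snp_positions = snp_positions),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d SNPs%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$snp_positions)) "" else " (with positions)"))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$values)

# Accept either a genotype_matrix or a bare 0/1/2 matrix everywhere.
.gvalues <- function(G) {
  if (inherits(G, "genotype_matrix")) return(G$values)
  genotype_matrix(G)$values
}

#' Read genotypes from a matrix TSV or a VCF file
#'
#' The matrix format is tab-separated: a header row of SNP ids, then one
#' row per sample beginning with the sample id followed by integer
#' genotypes.  VCF v4.x files are read through the `GT` field of biallelic
#' diploid records: `0/0 -> 0`, `0/1` or `1/0 -> 1`, `1/1 -> 2` (phased
#' separators accepted); multi-allelic records are skipped with a warning.
#'
#' @param path file path.
#' @param format `"matrix-tsv"` or `"vcf"`.
#' @param missing_policy what to do with missing genotypes:
#'   `"mode-impute"` (default; replace by the SNP's most frequent genotype,
#'   smaller genotype on ties), `"drop-snp"` (remove SNPs with any missing
#'   call), or `"fail"`.
#' @return A [genotype_matrix].
#' @export
read_genotypes <- function(path, format = c("matrix-tsv", "vcf"),
                           missing_policy = c("mode-impute", "fail",
                                              "drop-snp")) {
  format <- match.arg(format)
  missing_policy <- match.arg(missing_policy)
  .assert(file.exists(path), "file not found: %s", path)
  if (format == "matrix-tsv") {
    .read_genotype_tsv(path, missing_policy)
  } else {
    .read_genotype_vcf(path, missing_policy)
  }
}

.read_genotype_tsv <- function(path, missing_policy) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  .assert(length(lines) >= 2L, "genotype file %s has no data rows", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  snp_ids <- header[-1L]
  d <- length(snp_ids)
  .assert(d >= 1L, "genotype file %s: header has no SNP columns", path)
  n <- length(lines) - 1L
  vals <- matrix(NA_integer_, n, d)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    toks <- strsplit(lines[[i + 1L]], "\t", fixed = TRUE)[[1L]]
    if (length(toks) != d + 1L)
      stop(sprintf("parse error in %s line %d: expected %d fields, found %d",
                   path, i + 1L, d + 1L, length(toks)), call. = FALSE)
    sample_ids[i] <- toks[1L]
    cells <- toks[-1L]
    miss <- cells %in% c("", ".", "NA")
    g <- suppressWarnings(as.integer(cells))
    bad <- which(!miss & (is.na(g) | !(g %in% 0:2)))
    if (length(bad) && missing_policy == "fail")
      stop(sprintf("validation error in %s line %d: genotype '%s' not in {0,1,2}",
                   path, i + 1L, cells[bad[1L]]), call. = FALSE)
    g[miss | (is.na(g) | !(g %in% 0:2))] <- NA_integer_
    vals[i, ] <- g
  }
  .apply_missing_policy(vals, snp_ids, sample_ids, NULL, missing_policy, path)
}

.read_genotype_vcf <- function(path, missing_policy) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"], fixed = TRUE)
  if (any(multi)) {
    warning(sprintf("skipping %d multi-allelic VCF record(s)", sum(multi)))
  }
  keep <- which(!multi)
  .assert(length(keep) >= 1L, "no biallelic records in %s", path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = 1L, dimnames = list(
    rownames = NULL, colnames = colnames(vcf@gt)[-1L]))
  gt <- gt[keep, , drop = FALSE]
  code <- matrix(NA_integer_, nrow(gt), ncol(gt))
  norm <- gsub("|", "/", gt, fixed = TRUE)
  code[norm %in% "0/0"] <- 0L
  code[norm %in% c("0/1", "1/0")] <- 1L
  code[norm %in% "1/1"] <- 2L
  unknown <- !is.na(gt) & is.na(code) & !(norm %in% c("./.", "."))
  .assert(!any(unknown), "unsupported GT value '%s' in %s",
          gt[which(unknown)[1L]], path)
  snp_ids <- fix[keep, "ID"]
  noid <- is.na(snp_ids) | snp_ids == "."
  snp_ids[noid] <- paste0(fix[keep, "CHROM"], ":", fix[keep, "POS"])[noid]
  pos <- data.frame(chrom = fix[keep, "CHROM"],
                    pos = as.integer(fix[keep, "POS"]),
                    stringsAsFactors = FALSE)
  .apply_missing_policy(t(code), snp_ids, colnames(gt), pos,
                        missing_policy, path)
}

.apply_missing_policy <- function(vals, snp_ids, sample_ids, pos,
                                  missing_policy, path) {
  if (anyNA(vals)) {
    if (missing_policy == "fail") {
      stop(sprintf("validation error: missing genotypes in %s", path),
           call. = FALSE)
    } else if (missing_policy == "drop-snp") {
      drop <- which(colSums(is.na(vals)) > 0L)
      warning(sprintf("dropping %d SNP(s) with missing genotypes", length(drop)))
      .assert(length(drop) < ncol(vals), "all SNPs have missing genotypes")
      vals <- vals[, -drop, drop = FALSE]
      snp_ids <- snp_ids[-drop]
      if (!is.null(pos)) pos <- pos[-drop, , drop = FALSE]
    } else {  # mode-impute
      n_imp <- sum(is.na(vals))
      for (j in which(colSums(is.na(vals)) > 0L)) {
        obs <- vals[, j][!is.na(vals[, j])]
        mode_g <- if (length(obs)) {
          tab <- tabulate(obs + 1L, nbins = 3L)
          which.max(tab) - 1L  # smaller genotype wins ties
        } else 0L
        vals[is.na(vals[, j]), j] <- mode_g
      }
      warning(sprintf("mode-imputed %d missing genotype(s)", n_imp))
    }
  }
  genotype_matrix(vals, snp_ids = snp_ids, sample_ids = sample_ids,
                  snp_positions = pos)
}

#' Write genotypes as a matrix TSV
#'
#' Inverse of [read_genotypes()] for the `matrix-tsv` format; a write
#' followed by a read reproduces the matrix exactly.
#'
#' @param G a [genotype_matrix] (or bare 0/1/2 matrix).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(G, path) {
  if (!inherits(G, "genotype_matrix")) G <- genotype_matrix(G)
  lines <- c(paste(c("sample_id", G$snp_ids), collapse = "\t"),
             vapply(seq_along(G$sample_ids), function(i)
               paste(c(G$sample_ids[i], G$values[i, ]), collapse = "\t"),
               character(1L)))
  writeLines(lines, path)
  invisible(path)
}

#' Read a binary phenotype TSV
#'
#' Expects a tab-separated file with a header and columns `sample_id` and
#' `status` (1 = case, 0 = control).
#'
#' @param path file path.
#' @return Named integer vector of 0/1 status, names = sample ids.
#' @export
read_phenotype <- function(path) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  .assert(all(c("sample_id", "status") %in% names(df)),
          "phenotype file %s must have columns sample_id and status", path)
  y <- as.integer(df$status)
  names(y) <- as.character(df$sample_id)
  validate_phenotype(y)
  y
}

#' Validate a binary phenotype vector
#'
#' @param y integer vector of 0/1 (1 = case); optionally named by sample id.
#' @return `y` invisibly; errors if invalid.
#' @export
validate_phenotype <- function(y) {
  .assert(is.numeric(y) && !anyNA(y) && all(y %in% c(0, 1)),
          "phenotype entries must be 0 or 1")
  .assert(any(y == 1) && any(y == 0),
          "phenotype needs at least one case and one control")
  invisible(y)
}

#' Construct a SNP set
#'
#' A named collection of genotype-matrix column indices (1-based, the R
#' convention) representing the SNPs of a gene or pathway.
#'
#' @param set_id identifier.
#' @param snp_indices integer vector of unique column indices.
#' @param d optional total SNP count for bound checking.
#' @return An object of class `snp_set`.
#' @export
snp_set <- function(set_id, snp_indices, d = NULL) {
  snp_indices <- as.integer(snp_indices)
  .assert(length(snp_indices) >= 1L, "snp_set '%s' is empty", set_id)
  .assert(!anyDuplicated(snp_indices), "snp_set '%s' has duplicate indices",
          set_id)
  .assert(all(snp_indices >= 1L), "snp_set '%s': indices must be >= 1", set_id)
  if (!is.null(d))
    .assert(all(snp_indices <= d), "snp_set '%s': index out of range", set_id)
  structure(list(set_id = as.character(set_id),
                 snp_indices = sort(snp_indices)),
            class = "snp_set")
}

#' @export
print.snp_set <- function(x, ...) {
  cat(sprintf("snp_set '%s': %d SNPs\n", x$set_id, length(x$snp_indices)))
  invisible(x)
}

#' Read gene intervals from a BED-like file
#'
#' Tab-separated columns `chrom`, `start`, `end`, `gene_id`, no header.
#' BED coordinates (0-based half-open) are converted at read time to the
#' 1-based inclusive convention used internally; set `zero_based = FALSE`
#' if the file is already 1-based inclusive.
#'
#' @param path file path.
#' @param zero_based logical; input uses BED 0-based half-open coordinates.
#' @return data.frame(gene_id, chrom, start, end), 1-based inclusive.
#' @export
read_gene_intervals <- function(path, zero_based = TRUE) {
  .assert(file.exists(path), "file not found: %s", path)
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  .assert(ncol(df) >= 4L, "gene interval file %s needs 4 columns", path)
  out <- data.frame(gene_id = as.character(df[[4L]]),
                    chrom = as.character(df[[1L]]),
                    start = as.integer(df[[2L]]) + if (zero_based) 1L else 0L,
                    end = as.integer(df[[3L]]),
                    stringsAsFactors = FALSE)
  .assert(all(out$start <= out$end), "gene interval with start > end in %s",
          path)
  out
}

#' Assign SNPs to genes within a flanking window
#'
#' A SNP is assigned to a gene if its position lies in
#' `[start - window_bp, end + window_bp]`, boundaries inclusive, on the
#' same chromosome.  A SNP may belong to several genes.
#'
#' @param snp_positions data.frame(chrom, pos), one row per genotype
#'   column, in column order (e.g. `G$snp_positions`).
#' @param genes data.frame as returned by [read_gene_intervals()].
#' @param window_bp flanking window in base pairs (default 5000).
#' @return Named list of [snp_set] objects, one per gene with at least one
#'   assigned SNP; empty list (with a warning) if nothing maps.
#' @export
map_snps_to_genes <- function(snp_positions, genes, window_bp = 5000L) {
  .assert(is.data.frame(snp_positions) &&
            all(c("chrom", "pos") %in% names(snp_positions)),
          "snp_positions must be a data.frame(chrom, pos)")
  .assert(window_bp >= 0, "window_bp must be non-negative")
  sets <- list()
  for (r in seq_len(nrow(genes))) {
    hit <- which(snp_positions$chrom == genes$chrom[r] &
                   snp_positions$pos >= genes$start[r] - window_bp &
                   snp_positions$pos <= genes$end[r] + window_bp)
    if (length(hit))
      sets[[genes$gene_id[r]]] <- snp_set(genes$gene_id[r], hit,
                                          d = nrow(snp_positions))
  }
  if (!length(sets)) warning("no SNP maps to any gene")
  sets
}

#' Read pathway gene sets from a GMT file
#'
#' GMT lines are tab-separated: set name, description, then member gene
#' symbols.  Pathways with more than `gene_sets_max` genes are removed
#' (overly broad sets hurt specificity); input order is preserved.
#'
#' @param path file path.
#' @param gene_sets_max maximum gene count retained (default 250; a set
#'   with exactly 250 genes is kept).
#' @return Named list of character vectors of gene ids; descriptions in
#'   attribute `"description"`.
#' @export
read_gmt_pathways <- function(path, gene_sets_max = 250L) {
  .assert(file.exists(path), "file not found: %s", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  .assert(length(lines) >= 1L, "GMT file %s is empty", path)
  out <- list(); desc <- character()
  for (i in seq_along(lines)) {
    toks <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(toks) < 3L)
      stop(sprintf("parse error in %s line %d: GMT lines need name, description and at least one gene",
                   path, i), call. = FALSE)
    genes <- unique(toks[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (length(genes) > gene_sets_max) next
    out[[toks[1L]]] <- genes
    desc[toks[1L]] <- toks[2L]
  }
  attr(out, "description") <- desc
  out
}

#' Build pathway-level SNP sets from gene-level SNP sets
#'
#' Pathway SNP set = union (deduplicated) of its member genes' SNP
#' indices.  Pathways with no mapped SNPs are dropped with a warning.
#'
#' @param pathways named list of gene-id vectors ([read_gmt_pathways()]).
#' @param gene_snpsets named list of gene [snp_set]s
#'   ([map_snps_to_genes()]).
#' @return Named list of pathway [snp_set]s.
#' @export
pathway_snpsets <- function(pathways, gene_snpsets) {
  out <- list()
  dropped <- character()
  for (pw in names(pathways)) {
    members <- intersect(pathways[[pw]], names(gene_snpsets))
    idx <- sort(unique(unlist(lapply(gene_snpsets[members],
                                     function(s) s$snp_indices))))
    if (length(idx)) out[[pw]] <- snp_set(pw, idx)
    else dropped <- c(dropped, pw)
  }
  if (length(dropped))
    warning(sprintf("dropped %d pathway(s) with no mapped SNPs",
                    length(dropped)))
  out
}
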