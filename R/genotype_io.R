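# PLINK binary genotype I/O, population label files, and Q/P estimate files.

GENO_MISSING <- NA_integer_

#' Construct a genotype matrix object
#'
#' Container for diploid biallelic SNP genotypes: an I x J integer matrix of
#' counted-allele dosages with entries in \{0, 1, 2\} or `NA` (missing), plus
#' individual and marker identifiers and per-marker allele labels. The count
#' `n_ij` is the number of copies of the A1 ("type 1") allele carried by
#' individual `i` at marker `j`.
#'
#' @param counts integer matrix, I individuals x J markers, entries in
#'   \{0, 1, 2, NA\}.
#' @param individual_ids character vector of length I.
#' @param marker_ids character vector of length J.
#' @param allele1,allele2 per-marker allele labels (length J); `allele1` is the
#'   counted allele.
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(counts,
                            individual_ids = NULL,
                            marker_ids = NULL,
                            allele1 = NULL,
                            allele2 = NULL) {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "integer"
  I <- nrow(counts)
  J <- ncol(counts)
  if (I < 1L || J < 1L) stop("genotype matrix must have at least one individual and one marker")
  bad <- counts[!is.na(counts)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L))) {
    stop("genotype counts must be 0, 1, 2 or NA")
  }
  individual_ids <- individual_ids %||% paste0("ind", seq_len(I))
  marker_ids <- marker_ids %||% paste0("snp", seq_len(J))
  allele1 <- allele1 %||% rep("A", J)
  allele2 <- allele2 %||% rep("B", J)
  if (length(individual_ids) != I) stop("individual_ids length does not match row count")
  if (length(marker_ids) != J) stop("marker_ids length does not match column count")
  if (length(allele1) != J || length(allele2) != J) stop("allele labels must have one entry per marker")
  structure(
    list(counts = counts,
         individual_ids = as.character(individual_ids),
         marker_ids = as.character(marker_ids),
         allele1 = as.character(allele1),
         allele2 = as.character(allele2)),
    class = "genotype_matrix"
  )
}

#' @export
print.genotype_matrix <- function(x, ...) {
  nmiss <- sum(is.na(x$counts))
  cat(sprintf("genotype_matrix: %d individuals x %d markers (%d missing entries)\n",
              nrow(x$counts), ncol(x$counts), nmiss))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$counts)

# Extract the integer count matrix (with masking applied, for masked objects).
#' Genotype count matrix accessor
#'
#' Returns the I x J integer dosage matrix of a [genotype_matrix()] or
#' [mask_genotypes()] object, with masked entries reported as `NA`.
#'
#' @param x a `genotype_matrix` or `masked_genotypes` object (a bare integer
#'   matrix is passed through).
#' @return Integer matrix with entries in \{0, 1, 2, NA\}.
#' @export
geno_counts <- function(x) {
  if (inherits(x, "masked_genotypes")) return(x$counts)
  if (inherits(x, "genotype_matrix")) return(x$counts)
  if (is.matrix(x)) {
    storage.mode(x) <- "integer"
    return(x)
  }
  stop("cannot extract genotype counts from an object of class ", paste(class(x), collapse = "/"))
}

# ---------------------------------------------------------------------------
# PLINK .bed/.bim/.fam
# ---------------------------------------------------------------------------

# 2-bit PLINK codes within a byte (least significant pair = first individual):
# 00 -> 2 copies of A1, 01 -> missing, 10 -> 1 copy, 11 -> 0 copies.
plink_code_to_count <- c(2L, NA_integer_, 1L, 0L)
plink_count_to_code <- function(n) {
  code <- integer(length(n))
  code[is.na(n)] <- 1L
  code[!is.na(n) & n == 2L] <- 0L
  code[!is.na(n) & n == 1L] <- 2L
  code[!is.na(n) & n == 0L] <- 3L
  code
}

# 256 x 4 lookup: byte value -> allele counts of its four 2-bit slots
plink_byte_lut <- local({
  b <- 0:255
  codes <- cbind(b %% 4L, (b %/% 4L) %% 4L, (b %/% 16L) %% 4L, (b %/% 64L) %% 4L)
  matrix(plink_code_to_count[codes + 1L], nrow = 256L)
})

#' Read PLINK binary genotypes
#'
#' Reads a SNP-major PLINK 1 binary fileset (`.bed` + `.bim` + `.fam`) into a
#' [genotype_matrix()]. The dosage `n_ij` counts the A1 allele of the `.bim`
#' file. Only the SNP-major dialect (mode byte `0x01`) is supported;
#' individual-major files are rejected.
#'
#' @param bed_path path to the `.bed` file.
#' @param bim_path,fam_path paths to the companion files; default replaces the
#'   `.bed` extension.
#' @return A `genotype_matrix`.
#' @export
read_plink_bed <- function(bed_path,
                           bim_path = sub("\\.bed$", ".bim", bed_path),
                           fam_path = sub("\\.bed$", ".fam", bed_path)) {
  for (p in c(bed_path, bim_path, fam_path)) {
    if (!file.exists(p)) stop("missing PLINK file: ", p)
  }
  bim <- read.table(bim_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(bim) < 6L) stop(".bim file must have 6 columns")
  fam <- read.table(fam_path, header = FALSE, stringsAsFactors = FALSE,
                    colClasses = "character")
  if (ncol(fam) < 6L) stop(".fam file must have 6 columns")
  J <- nrow(bim)
  I <- nrow(fam)
  raw <- readBin(bed_path, what = "raw", n = file.info(bed_path)$size)
  if (length(raw) < 3L || raw[1] != as.raw(0x6c) || raw[2] != as.raw(0x1b)) {
    stop("not a PLINK .bed file (bad magic bytes): ", bed_path)
  }
  if (raw[3] == as.raw(0x00)) {
    stop("individual-major .bed files are not supported (mode byte 0x00): ", bed_path)
  }
  if (raw[3] != as.raw(0x01)) stop("unrecognized .bed mode byte: ", bed_path)
  B <- ceiling(I / 4)
  body <- raw[-(1:3)]
  if (length(body) != B * J) {
    stop(sprintf(".bed is truncated or inconsistent: expected %d data bytes (ceil(%d/4) x %d), found %d",
                 B * J, I, J, length(body)))
  }
  dec <- t(plink_byte_lut[as.integer(body) + 1L, , drop = FALSE]) # 4 x (B*J)
  dim(dec) <- c(4L * B, J)
  counts <- dec[seq_len(I), , drop = FALSE]
  genotype_matrix(counts,
                  individual_ids = fam[[2]],
                  marker_ids = bim[[2]],
                  allele1 = bim[[5]],
                  allele2 = bim[[6]])
}

#' Write PLINK binary genotypes
#'
#' Writes a [genotype_matrix()] as a SNP-major PLINK 1 binary fileset. Exact
#' round-trip with [read_plink_bed()] of counts and missingness.
#'
#' @param genotypes a `genotype_matrix`.
#' @param path_prefix output prefix; `.bed`, `.bim`, `.fam` are appended.
#' @return The prefix, invisibly.
#' @export
write_plink_bed <- function(genotypes, path_prefix) {
  stopifnot(inherits(genotypes, "genotype_matrix"))
  counts <- genotypes$counts
  I <- nrow(counts)
  J <- ncol(counts)
  B <- ceiling(I / 4)
  codes <- matrix(0L, nrow = 4L * B, ncol = J)
  codes[seq_len(I), ] <- matrix(plink_count_to_code(counts), nrow = I)
  s <- seq(1L, 4L * B, by = 4L)
  bytes <- codes[s, , drop = FALSE] +
    4L * codes[s + 1L, , drop = FALSE] +
    16L * codes[s + 2L, , drop = FALSE] +
    64L * codes[s + 3L, , drop = FALSE]
  con <- file(paste0(path_prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(as.raw(as.vector(bytes)), con)
  bim <- data.frame(chrom = 1L,
                    id = genotypes$marker_ids,
                    cm = 0L,
                    pos = seq_len(J),
                    a1 = genotypes$allele1,
                    a2 = genotypes$allele2)
  write.table(bim, paste0(path_prefix, ".bim"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  fam <- data.frame(fid = genotypes$individual_ids,
                    iid = genotypes$individual_ids,
                    pat = 0L, mat = 0L, sex = 0L, pheno = -9L)
  write.table(fam, paste0(path_prefix, ".fam"), quote = FALSE, sep = "\t",
              row.names = FALSE, col.names = FALSE)
  invisible(path_prefix)
}

# ---------------------------------------------------------------------------
# Population label (.ind) files
# ---------------------------------------------------------------------------

#' Construct population labels
#'
#' Per-individual optional population assignments used by the supervised mode.
#' Unlabeled individuals (assignment `NA`) are the ones whose ancestry is
#' estimated; labeled individuals serve as references.
#'
#' @param assignments character vector, one entry per individual; `NA` for
#'   unlabeled.
#' @param population_names ordered unique population names; default: order of
#'   first appearance.
#' @return An object of class `population_labels`.
#' @export
population_labels <- function(assignments, population_names = NULL) {
  assignments <- as.character(assignments)
  seen <- unique(assignments[!is.na(assignments)])
  if (length(seen) == 0L) stop("no labeled individuals: supervised mode needs at least one reference")
  population_names <- population_names %||% seen
  if (!setequal(seen, population_names)) {
    stop("population_names must match the labels present in assignments")
  }
  structure(list(assignments = assignments,
                 population_names = as.character(population_names)),
            class = "population_labels")
}

#' @export
print.population_labels <- function(x, ...) {
  cat(sprintf("population_labels: %d individuals, %d populations (%s), %d unlabeled\n",
              length(x$assignments), length(x$population_names),
              paste(x$population_names, collapse = ", "),
              sum(is.na(x$assignments))))
  invisible(x)
}

#' Read a population label (.ind) file
#'
#' One label per line, aligned with the `.fam` individual order. The token
#' `"-"` marks an unlabeled individual; any other token is a population name.
#'
#' @param path path to the `.ind` file.
#' @param individual_ids individual identifiers (used only to check alignment).
#' @return A [population_labels()] object.
#' @export
read_ind_file <- function(path, individual_ids) {
  lines <- trimws(readLines(path))
  if (length(lines) && !nzchar(lines[length(lines)])) lines <- lines[-length(lines)]
  if (length(lines) != length(individual_ids)) {
    stop(sprintf(".ind file has %d lines but there are %d individuals",
                 length(lines), length(individual_ids)))
  }
  assignments <- ifelse(lines == "-", NA_character_, lines)
  population_labels(assignments)
}

#' Write a population label (.ind) file
#'
#' @param labels a [population_labels()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ind_file <- function(labels, path) {
  stopifnot(inherits(labels, "population_labels"))
  writeLines(ifelse(is.na(labels$assignments), "-", labels$assignments), path)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Q / P estimate files
# ---------------------------------------------------------------------------

#' Write estimated ancestry fractions and allele frequencies
#'
#' Writes `prefix.K.Q` (one row per individual, one column per population) and
#' `prefix.K.P` (one row per marker, one column per population) as
#' whitespace-delimited text with 6 decimal places.
#'
#' @param Q I x K row-stochastic ancestry matrix.
#' @param F_mat K x J allele-frequency matrix.
#' @param path_prefix output prefix.
#' @param K number of populations (defaults to `ncol(Q)`).
#' @return Character vector of the two file paths, invisibly.
#' @export
write_estimates <- function(Q, F_mat, path_prefix, K = ncol(Q)) {
  Q <- as.matrix(Q)
  F_mat <- as.matrix(F_mat)
  if (ncol(Q) != K || nrow(F_mat) != K) {
    stop("dimension mismatch: Q must be I x K and F K x J")
  }
  qfile <- sprintf("%s.%d.Q", path_prefix, K)
  pfile <- sprintf("%s.%d.P", path_prefix, K)
  write.table(format(Q, nsmall = 6, digits = 6, scientific = FALSE, trim = TRUE),
              qfile, quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(format(t(F_mat), nsmall = 6, digits = 6, scientific = FALSE, trim = TRUE),
              pfile, quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(c(Q = qfile, P = pfile))
}

#' Read estimate files written by [write_estimates()]
#'
#' @param path_prefix prefix used when writing.
#' @param K number of populations in the file names.
#' @return List with elements `Q` (I x K) and `F` (K x J).
#' @export
read_estimates <- function(path_prefix, K) {
  Q <- as.matrix(read.table(sprintf("%s.%d.Q", path_prefix, K)))
  P <- as.matrix(read.table(sprintf("%s.%d.P", path_prefix, K)))
  dimnames(Q) <- NULL
  dimnames(P) <- NULL
  list(Q = Q, F = t(P))
}
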