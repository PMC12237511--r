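# PLINK 1 binary trio (.bed/.bim/.fam) reader and writer.
#
# .bed layout: 3 header bytes (0x6C 0x1B magic, then the mode byte: 0x01 =
# SNP-major), followed by one record of ceiling(n/4) bytes per variant.  Each
# byte packs four samples, lowest-order bit pair first:
#   00 -> 2 copies of allele 1   10 -> heterozygous (1)
#   11 -> 0 copies of allele 1   01 -> missing
# Trailing unused bit pairs in the last byte of a record are zero on write
# and ignored on read.

# 256 x 4 lookup: byte value + 1 -> the four additive codes (NA = missing).
.bed_pair_code <- c(2L, NA_integer_, 1L, 0L)    # bit-pair values 0,1,2,3
.bed_decode_lut <- local({
  b <- 0:255
  cbind(
    .bed_pair_code[bitwAnd(b, 3L) + 1L],
    .bed_pair_code[bitwAnd(bitwShiftR(b, 2L), 3L) + 1L],
    .bed_pair_code[bitwAnd(bitwShiftR(b, 4L), 3L) + 1L],
    .bed_pair_code[bitwAnd(bitwShiftR(b, 6L), 3L) + 1L]
  )
})
# code -> bit-pair value; index by code + 1 (missing handled separately)
.bed_encode_pair <- c(3L, 2L, 0L)

#' Decode one SNP-major .bed byte
#'
#' Unpacks the four additive allele-count codes stored in a single byte of a
#' PLINK 1 SNP-major `.bed` file, lowest-order bit pair first. Bit pair
#' `00` decodes to 2 (homozygous for allele 1), `10` to 1 (heterozygous),
#' `11` to 0, and `01` to `NA` (missing).
#'
#' @param byte An integer in 0..255 (or a raw scalar).
#' @return An integer vector of length 4 with values 0, 1, 2 or `NA`.
#' @examples
#' decode_bed_byte(0x1B)  # 0 1 NA 2
#' @export
decode_bed_byte <- function(byte) {
  if (is.raw(byte)) byte <- as.integer(byte)
  stopifnot(length(byte) == 1L, byte >= 0, byte <= 255)
  .bed_decode_lut[byte + 1L, ]
}

#' Construct a genotype matrix
#'
#' Bundles an m x n matrix of additive allele-count codes (rows are variants,
#' columns are samples, entries 0/1/2 or `NA` for missing) with variant and
#' sample identifiers.
#'
#' @param codes Integer matrix of allele counts in \{0, 1, 2, NA\}.
#' @param snp_ids Character vector of m unique variant identifiers.
#' @param sample_ids Character vector of n sample identifiers.
#' @return A `genotype_matrix` object.
#' @export
genotype_matrix <- function(codes, snp_ids = rownames(codes),
                            sample_ids = colnames(codes)) {
  codes <- as.matrix(codes)
  storage.mode(codes) <- "integer"
  if (nrow(codes) < 1L || ncol(codes) < 1L) {
    stop("genotype matrix must have at least one variant and one sample",
         call. = FALSE)
  }
  bad <- !(codes %in% c(0L, 1L, 2L) | is.na(codes))
  if (any(bad)) {
    stop("genotype codes must be 0, 1, 2 or NA; found ",
         paste(unique(codes[bad]), collapse = ", "), call. = FALSE)
  }
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(nrow(codes)))
  if (is.null(sample_ids)) sample_ids <- paste0("sample_", seq_len(ncol(codes)))
  stopifnot(length(snp_ids) == nrow(codes),
            length(sample_ids) == ncol(codes))
  if (anyDuplicated(snp_ids)) {
    stop("variant identifiers must be unique", call. = FALSE)
  }
  rownames(codes) <- as.character(snp_ids)
  colnames(codes) <- as.character(sample_ids)
  structure(list(codes = codes), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("<genotype_matrix> %d variants x %d samples (%.2f%% missing)\n",
              nrow(x$codes), ncol(x$codes),
              100 * mean(is.na(x$codes))))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$codes)

.codes_of <- function(geno) {
  if (inherits(geno, "plink_data")) geno <- geno$genotypes
  if (inherits(geno, "genotype_matrix")) return(geno$codes)
  if (is.matrix(geno)) {
    storage.mode(geno) <- "integer"
    return(geno)
  }
  stop("expected a genotype_matrix, plink_data or codes matrix", call. = FALSE)
}

.bed_record_bytes <- function(n_samples) as.integer(ceiling(n_samples / 4))

#' Read a PLINK 1 binary trio
#'
#' Reads `<prefix>.bed`, `<prefix>.bim` and `<prefix>.fam` into a genotype
#' matrix plus variant and sample tables. Only SNP-major `.bed` files (mode
#' byte `0x01`) are supported; sample-major files are rejected.
#'
#' @param prefix Path prefix of the trio (without extension).
#' @return A `plink_data` list with elements `genotypes`
#'   ([genotype_matrix()]), `variants` (tibble with the six .bim columns:
#'   `chrom`, `snp_id`, `cm`, `pos`, `allele1`, `allele2`) and `samples`
#'   (tibble with the six .fam columns: `fid`, `iid`, `pid`, `mid`, `sex`,
#'   `phenotype`). The additive code counts copies of allele 1 (A1), the
#'   conventional PLINK orientation; the F statistic and all permutation
#'   p-values are invariant to flipping alleles.
#' @export
read_plink <- function(prefix) {
  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    stop("missing input file(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }

  bim <- utils::read.table(paths[2], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("chrom", "snp_id", "cm", "pos",
                                         "allele1", "allele2"),
                           colClasses = c("character", "character", "numeric",
                                          "integer", "character", "character"))
  bim <- tibble::as_tibble(bim)
  if (anyDuplicated(bim$snp_id)) {
    stop("duplicate variant identifiers in ", paths[2], call. = FALSE)
  }
  fam <- utils::read.table(paths[3], header = FALSE, stringsAsFactors = FALSE,
                           col.names = c("fid", "iid", "pid", "mid", "sex",
                                         "phenotype"),
                           colClasses = c("character", "character", "character",
                                          "character", "integer", "numeric"))
  fam <- tibble::as_tibble(fam)
  if (anyDuplicated(fam[, c("fid", "iid")])) {
    stop("duplicate (family ID, individual ID) pairs in ", paths[3],
         call. = FALSE)
  }

  m <- nrow(bim)
  n <- nrow(fam)
  raw <- readBin(paths[1], what = "raw", n = file.size(paths[1]))
  if (length(raw) < 3L || raw[1] != as.raw(0x6C) || raw[2] != as.raw(0x1B)) {
    stop(sprintf(
      ".bed format error: expected magic bytes 0x6C 0x1B, found 0x%02X 0x%02X",
      as.integer(raw[1]), as.integer(raw[2])), call. = FALSE)
  }
  if (raw[3] == as.raw(0x00)) {
    stop("unsupported layout: sample-major .bed (mode byte 0x00); ",
         "only SNP-major files are supported", call. = FALSE)
  }
  if (raw[3] != as.raw(0x01)) {
    stop(sprintf(".bed format error: unknown mode byte 0x%02X",
                 as.integer(raw[3])), call. = FALSE)
  }
  bpr <- .bed_record_bytes(n)
  expected <- 3 + as.double(m) * bpr
  if (length(raw) != expected) {
    stop(sprintf(
      ".bed truncation error: %d bytes found, %d expected for %d variants x %d samples",
      length(raw), expected, m, n), call. = FALSE)
  }

  body <- as.integer(raw[-(1:3)])
  decoded <- .bed_decode_lut[body + 1L, , drop = FALSE]  # (m*bpr) x 4
  decoded <- t(decoded)                                  # 4 x (m*bpr)
  dim(decoded) <- c(4L * bpr, m)                         # samples x variants
  codes <- t(decoded[seq_len(n), , drop = FALSE])

  geno <- genotype_matrix(codes, snp_ids = bim$snp_id,
                          sample_ids = paste(fam$fid, fam$iid, sep = "_"))
  structure(list(genotypes = geno, variants = bim, samples = fam),
            class = "plink_data")
}

#' @export
print.plink_data <- function(x, ...) {
  print(x$genotypes)
  invisible(x)
}

#' Write a PLINK 1 binary trio
#'
#' Writes a genotype matrix and its variant/sample tables as a SNP-major
#' `.bed/.bim/.fam` trio that [read_plink()] inverts exactly. The `.bed`
#' record for each variant occupies `ceiling(n/4)` bytes; unused trailing bit
#' pairs are written as zero.
#'
#' @param geno A [genotype_matrix()] (or `plink_data`, or codes matrix).
#' @param variants Variant table (six .bim columns); defaults are fabricated
#'   from the variant identifiers when omitted.
#' @param samples Sample table (six .fam columns); fabricated when omitted.
#' @param prefix Output path prefix.
#' @return The three file paths, invisibly.
#' @export
write_plink <- function(geno, prefix, variants = NULL, samples = NULL) {
  codes <- .codes_of(geno)
  m <- nrow(codes)
  n <- ncol(codes)
  snp_ids <- rownames(codes)
  if (is.null(snp_ids)) snp_ids <- paste0("snp_", seq_len(m))
  if (is.null(variants)) {
    variants <- tibble::tibble(chrom = "1", snp_id = snp_ids, cm = 0,
                               pos = seq_len(m), allele1 = "A", allele2 = "B")
  }
  if (is.null(samples)) {
    sid <- colnames(codes)
    if (is.null(sid)) sid <- paste0("sample_", seq_len(n))
    samples <- tibble::tibble(fid = sid, iid = sid, pid = "0", mid = "0",
                              sex = 0L, phenotype = -9)
  }
  stopifnot(nrow(variants) == m, nrow(samples) == n)

  bpr <- .bed_record_bytes(n)
  # pad each variant record to 4*bpr codes; pair value 0 (i.e. code 2) pads,
  # then overwrite: PLINK pads with zero BITS, i.e. pair value 0
  pair <- matrix(0L, nrow = 4L * bpr, ncol = m)
  cc <- t(codes)                             # n x m, column-major by variant
  pv <- ifelse(is.na(cc), 1L, .bed_encode_pair[cc + 1L])
  pair[seq_len(n), ] <- pv
  i1 <- seq(1L, 4L * bpr, by = 4L)
  bytes <- pair[i1, , drop = FALSE] +
    4L * pair[i1 + 1L, , drop = FALSE] +
    16L * pair[i1 + 2L, , drop = FALSE] +
    64L * pair[i1 + 3L, , drop = FALSE]

  paths <- paste0(prefix, c(".bed", ".bim", ".fam"))
  con <- file(paths[1], open = "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.raw(c(0x6C, 0x1B, 0x01)), con)
  writeBin(as.raw(bytes), con)

  utils::write.table(as.data.frame(variants)[, 1:6], paths[2],
                     quote = FALSE, sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(as.data.frame(samples)[, 1:6], paths[3],
                     quote = FALSE, sep = " ",
                     row.names = FALSE, col.names = FALSE)
  invisible(paths)
}

#' Read a PLINK-dialect covariate table
#'
#' Whitespace-delimited file whose first two columns are FID and IID and
#' whose remaining columns are numeric covariates (the PLINK `--covar`
#' dialect). An optional header line is detected by non-numeric entries in
#' the third column.
#'
#' @param path Covariate file path.
#' @return A tibble with `fid`, `iid` and one column per covariate.
#' @export
read_covar <- function(path) {
  if (!file.exists(path)) {
    stop("missing covariate file: ", path, call. = FALSE)
  }
  first <- utils::read.table(path, header = FALSE, nrows = 1,
                             stringsAsFactors = FALSE)
  header <- ncol(first) >= 3 && is.na(suppressWarnings(as.numeric(first[[3]])))
  tab <- utils::read.table(path, header = header, stringsAsFactors = FALSE)
  if (ncol(tab) < 3) {
    stop("covariate file needs FID, IID and at least one covariate column",
         call. = FALSE)
  }
  names(tab)[1:2] <- c("fid", "iid")
  if (!header) {
    names(tab)[-(1:2)] <- paste0("covar", seq_len(ncol(tab) - 2L))
  }
  for (j in seq(3, ncol(tab))) tab[[j]] <- as.numeric(tab[[j]])
  tibble::as_tibble(tab)
}

# Render a p-value (or any double) so that it parses back to the same float.
.fmt_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return("NA")
    if (!is.finite(v)) return(if (v > 0) "Inf" else "-Inf")
    format(v, digits = 17, scientific = NA, trim = TRUE)
  }, character(1))
  out
}

#' Write a per-variant result table
#'
#' Tab-delimited text with commented metadata header lines (`# key: value`),
#' a column-name line, and one row per variant. Numeric columns are rendered
#' with enough digits to parse back to the same double.
#'
#' @param rows A data frame of per-variant results.
#' @param path Output path.
#' @param metadata Named list written as commented header lines.
#' @return `path`, invisibly.
#' @export
write_results <- function(rows, path, metadata = NULL) {
  rows <- as.data.frame(rows)
  con <- file(path, open = "wt")
  on.exit(close(con), add = TRUE)
  for (key in names(metadata)) {
    writeLines(sprintf("# %s: %s", key, paste(metadata[[key]], collapse = " ")),
               con)
  }
  writeLines(paste(names(rows), collapse = "\t"), con)
  if (nrow(rows)) {
    cols <- lapply(rows, function(col) {
      if (is.double(col)) .fmt_num(col) else as.character(col)
    })
    writeLines(do.call(paste, c(cols, sep = "\t")), con)
  }
  invisible(path)
}

#' Read back a result table written by [write_results()]
#'
#' @param path Result file path.
#' @return A tibble; commented metadata lines are attached as the
#'   `"metadata"` attribute (character vector).
#' @export
read_results <- function(path) {
  lines <- readLines(path)
  meta <- grep("^#", lines, value = TRUE)
  tab <- utils::read.table(text = lines[!grepl("^#", lines)], header = TRUE,
                           sep = "\t", stringsAsFactors = FALSE)
  out <- tibble::as_tibble(tab)
  attr(out, "metadata") <- sub("^# ", "", meta)
  out
}
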