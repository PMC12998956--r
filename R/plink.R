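#' Read a PLINK 1.9 binary genotype triplet
#'
#' Decodes the SNP-major 2-bit `.bed` encoding together with the
#' `.bim` variant map and `.fam` sample roster.  Dosages count copies
#' of the A1 allele: byte codes 00 -> 2, 10 -> 1, 11 -> 0, 01 ->
#' missing (`NA`).
#'
#' @param prefix path prefix of the `.bed`/`.bim`/`.fam` files.
#' @return list with `genotypes` (`n x q` integer matrix, `NA` for
#'   missing), `bim` (columns `chr`, `id`, `cm`, `pos`, `a1`, `a2`),
#'   and `fam` (columns `fid`, `iid`, `pat`, `mat`, `sex`, `pheno`).
#' @export
read_plink <- function(prefix) {
  bim <- utils::read.table(paste0(prefix, ".bim"),
                           col.names = c("chr", "id", "cm", "pos",
                                         "a1", "a2"),
                           colClasses = c("character", "character",
                                          "numeric", "integer",
                                          "character", "character"))
  fam <- utils::read.table(paste0(prefix, ".fam"),
                           col.names = c("fid", "iid", "pat", "mat",
                                         "sex", "pheno"),
                           colClasses = c("character", "character",
                                          "character", "character",
                                          "integer", "numeric"))
  n <- nrow(fam); q <- nrow(bim)
  bps <- ceiling(n / 4)                     # bytes per SNP
  con <- file(paste0(prefix, ".bed"), "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 3L)
  if (!identical(as.integer(magic), c(0x6cL, 0x1bL, 0x01L)))
    stop("not a SNP-major PLINK bed file: ", prefix, ".bed")
  payload <- readBin(con, "raw", bps * q)
  if (length(payload) < bps * q) stop("truncated bed file")
  codes <- .bed_lut()[as.integer(payload) + 1L, , drop = FALSE]
  # codes: (bps*q) x 4 dosage values, rows = bytes in file order
  G <- matrix(t(codes), nrow = 4L * bps)[seq_len(n), , drop = FALSE]
  dim(G) <- c(n, q)
  colnames(G) <- bim$id
  list(genotypes = G, bim = bim, fam = fam)
}

# 256 x 4 lookup: byte -> dosages of its four 2-bit fields (LSB first)
.bed_lut <- function() {
  if (!is.null(.plink_env$lut)) return(.plink_env$lut)
  two_bit <- c(2L, NA_integer_, 1L, 0L)     # 00, 01, 10, 11
  b <- 0:255
  lut <- cbind(two_bit[b %% 4L + 1L],
               two_bit[(b %/% 4L) %% 4L + 1L],
               two_bit[(b %/% 16L) %% 4L + 1L],
               two_bit[(b %/% 64L) %% 4L + 1L])
  .plink_env$lut <- lut
  lut
}
.plink_env <- new.env(parent = emptyenv())

#' Write a PLINK 1.9 binary genotype triplet
#'
#' @param prefix output path prefix.
#' @param G `n x q` dosage matrix with entries 0/1/2 or `NA`.
#' @param bim optional variant map (defaults to chromosome 1,
#'   consecutive positions, alleles A/B).
#' @param fam optional sample roster (defaults to `F<i>`/`I<i>` ids).
#' @return the prefix, invisibly.
#' @export
write_plink <- function(prefix, G, bim = NULL, fam = NULL) {
  n <- nrow(G); q <- ncol(G)
  if (is.null(bim))
    bim <- data.frame(chr = 1L,
                      id = colnames(G) %||% paste0("snp", seq_len(q)),
                      cm = 0, pos = seq_len(q) * 1000L,
                      a1 = "A", a2 = "B")
  if (is.null(fam))
    fam <- data.frame(fid = paste0("F", seq_len(n)),
                      iid = paste0("I", seq_len(n)),
                      pat = 0, mat = 0, sex = 0, pheno = -9)
  utils::write.table(bim, paste0(prefix, ".bim"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(fam, paste0(prefix, ".fam"), sep = "\t",
                     quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  code <- matrix(3L, n, q)                  # dosage 0 -> code 11
  code[G == 1L] <- 2L                       # het -> 10
  code[G == 2L] <- 0L                       # hom A1 -> 00
  code[is.na(G)] <- 1L                      # missing -> 01
  bps <- ceiling(n / 4)
  pad <- matrix(3L, 4L * bps - n, q)        # pad codes are ignored
  C4 <- rbind(code, if (nrow(pad)) pad)
  dim(C4) <- c(4L, bps * q)
  bytes <- as.raw(C4[1L, ] + 4L * C4[2L, ] + 16L * C4[3L, ] +
                    64L * C4[4L, ])
  con <- file(paste0(prefix, ".bed"), "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x6c, 0x1b, 0x01)), con)
  writeBin(bytes, con)
  invisible(prefix)
}
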