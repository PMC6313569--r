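## Trio VCF reading/writing.
##
## Reading is backed by VariantAnnotation::readVcf; this layer enforces the
## trio contract (exactly three samples, in father/mother/proband order),
## decomposes multi-allelic sites into one record per alt allele, normalizes
## genotypes to "a/b" strings over {0,1,.}, and lifts the custom read-support
## FORMAT tags.
##
## Custom FORMAT tags (documented in the emitted header):
##   RL (Integer): read length of the reads supporting the variant allele;
##   RO (String):  pipe-separated 0-based offsets of the variant start
##                 within those reads.
## They let the edge-of-read indel filter run without any BAM access.

.TRIO_SAMPLES <- c("FATHER", "MOTHER", "PROBAND")

#' @noRd
vcf_header_lines <- function(path) {
  con <- file(path, "r")
  on.exit(close(con))
  n <- 0L
  repeat {
    l <- readLines(con, n = 1L)
    if (length(l) == 0L) .stopf("%s: no #CHROM header line", path)
    n <- n + 1L
    if (startsWith(l, "#CHROM")) return(n)
  }
}

#' Read a trio VCF
#'
#' Parses a VCF 4.2 file with exactly three samples, decomposing
#' multi-allelic sites into one variant record per alt allele.  Genotype
#' alleles are recoded against the record's alt: reference stays `0`, the
#' record's alt becomes `1`, any other alt allele of the original site
#' becomes missing for that record.  A genotype of `./.` is recorded as
#' missing, never as homozygous reference.
#'
#' @param path VCF file.
#' @param samples Expected sample names, in (father, mother, proband) order.
#' @return Data frame of trio variant records (one row per contig/pos/alt)
#'   with genotype, depth, genotype-quality, read-support and AF columns.
#' @export
read_trio_vcf <- function(path, samples = .TRIO_SAMPLES) {
  if (length(samples) != 3L) .stopf("a trio needs exactly three sample names")
  vcf <- suppressWarnings(VariantAnnotation::readVcf(path, genome = "synthetic"))
  have <- colnames(vcf)
  if (length(have) != 3L || !setequal(have, samples)) {
    miss <- setdiff(samples, have)
    .stopf("expected trio samples {%s}; file has {%s}%s",
           paste(samples, collapse = ","), paste(have, collapse = ","),
           if (length(miss)) paste0(" (missing ", paste(miss, collapse = ","), ")")
           else "")
  }
  vcf <- vcf[, samples]
  hdr_n <- vcf_header_lines(path)

  rr <- SummarizedExperiment::rowRanges(vcf)
  contig <- as.character(GenomeInfoDb::seqnames(rr))
  pos <- BiocGenerics::start(rr)
  ref <- as.character(rr$REF)
  alt_l <- VariantAnnotation::alt(vcf)
  n_alt <- S4Vectors::elementNROWS(alt_l)
  if (any(n_alt == 0L))
    .stopf("line %d: record with no ALT allele", hdr_n + which(n_alt == 0L)[1])

  g <- VariantAnnotation::geno(vcf)
  gt <- g$GT
  dp <- if ("DP" %in% names(g)) g$DP else matrix(NA_integer_, nrow(gt), 3)
  gq <- if ("GQ" %in% names(g)) g$GQ else matrix(NA_integer_, nrow(gt), 3)
  rl <- if ("RL" %in% names(g)) g$RL else matrix(NA_integer_, nrow(gt), 3)
  ro <- if ("RO" %in% names(g)) g$RO else matrix(NA_character_, nrow(gt), 3)
  ro[ro %in% c(".", "")] <- NA_character_

  info <- VariantAnnotation::info(vcf)
  af_l <- if ("AF" %in% names(info)) info$AF else NULL

  ## parse all genotypes once; validate tokens against per-site alt count
  parse_gt <- function(col, who) {
    toks <- strsplit(col, "[/|]")
    bad_len <- lengths(toks) != 2L
    if (any(bad_len))
      .stopf("line %d: malformed genotype '%s' for sample %s",
             hdr_n + which(bad_len)[1], col[which(bad_len)[1]], who)
    m <- matrix(unlist(toks), ncol = 2L, byrow = TRUE)
    ok_tok <- m == "." | grepl("^[0-9]+$", m)
    a <- suppressWarnings(matrix(as.integer(m), ncol = 2L))
    a[m == "."] <- NA_integer_
    bad <- !ok_tok[, 1] | !ok_tok[, 2] |
      (!is.na(a[, 1]) & a[, 1] > n_alt) | (!is.na(a[, 2]) & a[, 2] > n_alt)
    if (any(bad))
      .stopf("line %d: malformed genotype '%s' for sample %s",
             hdr_n + which(bad)[1], col[which(bad)[1]], who)
    a
  }
  al <- lapply(1:3, function(j) parse_gt(gt[, j], samples[j]))

  ## decomposition: one output row per (site, alt index)
  site <- rep(seq_along(n_alt), n_alt)
  aidx <- sequence(n_alt)
  alt <- unlist(lapply(seq_along(n_alt),
                       function(i) as.character(alt_l[[i]])), use.names = FALSE)

  recode <- function(a) {
    ## a: n_site x 2 integer alleles; recode per expanded record
    x1 <- a[site, 1]; x2 <- a[site, 2]
    r1 <- ifelse(is.na(x1), NA_integer_,
                 ifelse(x1 == 0L, 0L, ifelse(x1 == aidx, 1L, NA_integer_)))
    r2 <- ifelse(is.na(x2), NA_integer_,
                 ifelse(x2 == 0L, 0L, ifelse(x2 == aidx, 1L, NA_integer_)))
    both <- !is.na(r1) & !is.na(r2)
    a1 <- ifelse(both, pmin(r1, r2), r1)
    a2 <- ifelse(both, pmax(r1, r2), r2)
    paste(ifelse(is.na(a1), ".", a1), ifelse(is.na(a2), ".", a2), sep = "/")
  }
  gt_cols <- lapply(al, recode)

  af <- if (!is.null(af_l)) {
    unlist(lapply(seq_along(n_alt), function(i) {
      v <- af_l[[i]]
      if (length(v) < n_alt[i]) rep(NA_real_, n_alt[i]) else v[seq_len(n_alt[i])]
    }), use.names = FALSE)
  } else rep(NA_real_, length(site))

  out <- data.frame(
    contig = contig[site], pos = pos[site],
    ref = ref[site], alt = alt,
    vtype = variant_type(ref[site], alt),
    gt_father = gt_cols[[1]], gt_mother = gt_cols[[2]],
    gt_proband = gt_cols[[3]],
    dp_father = dp[site, 1], dp_mother = dp[site, 2], dp_proband = dp[site, 3],
    gq_father = gq[site, 1], gq_mother = gq[site, 2], gq_proband = gq[site, 3],
    rl_proband = rl[site, 3], ro_proband = ro[site, 3],
    af = af,
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Write a trio VCF
#'
#' Emits a VCF 4.2 file with samples in (father, mother, proband) order and
#' the package's read-support FORMAT tags.
#'
#' @param variants Trio variant data frame (see [read_trio_vcf()]).
#' @param path Output path.
#' @param contigs Named integer vector of contig lengths for the header.
#' @param samples Sample names, (father, mother, proband) order.
#' @export
write_trio_vcf <- function(variants, path, contigs = NULL,
                           samples = .TRIO_SAMPLES) {
  v <- variants[order(match(variants$contig, unique(variants$contig)),
                      variants$pos), , drop = FALSE]
  num <- function(x) ifelse(is.na(x), ".", as.character(x))
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(contigs))
      sprintf("##contig=<ID=%s,length=%d>", names(contigs),
              as.integer(contigs)),
    "##INFO=<ID=AF,Number=A,Type=Float,Description=\"Population allele frequency of the alt allele\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    "##FORMAT=<ID=GQ,Number=1,Type=Integer,Description=\"Genotype quality\">",
    "##FORMAT=<ID=RL,Number=1,Type=Integer,Description=\"Length of reads supporting the variant allele\">",
    "##FORMAT=<ID=RO,Number=1,Type=String,Description=\"Pipe-separated 0-based offsets of the variant start within supporting reads\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t")
  )
  fmt_sample <- function(gt, dp, gq, rl, ro) {
    paste(gt, num(dp), num(gq), num(rl), num(ro), sep = ":")
  }
  info <- ifelse(is.na(v$af), ".", sprintf("AF=%.17g", v$af))
  na_chr <- rep(NA_character_, nrow(v))
  na_int <- rep(NA_integer_, nrow(v))
  body <- paste(
    v$contig, v$pos, ".", v$ref, v$alt, ".", "PASS", info,
    "GT:DP:GQ:RL:RO",
    fmt_sample(v$gt_father, v$dp_father, v$gq_father, na_int, na_chr),
    fmt_sample(v$gt_mother, v$dp_mother, v$gq_mother, na_int, na_chr),
    fmt_sample(v$gt_proband, v$dp_proband, v$gq_proband,
               v$rl_proband %||% na_int, v$ro_proband %||% na_chr),
    sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}
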