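#' A panel of jointly called variants across MA lines
#'
#' The central small-variant container: one row per (contig, position, alt)
#' after multiallelic splitting, with the six site-level annotations used by
#' the hard filters and per-line genotype evidence. Positions are 1-based
#' (VCF convention); see [point_to_interval()] for the interval view.
#'
#' @param variants Data frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, and numeric columns `MQ`, `QD`, `FS`, `SOR`, `MQRankSum`,
#'   `ReadPosRankSum` (NA = annotation absent at that site).
#' @param gt Character matrix (variants x lines) with entries in
#'   `c("hom_ref", "het", "hom_alt", "missing")`.
#' @param ad Integer matrix of reads supporting the row's alt allele
#'   (NA where genotype is missing).
#' @param dp Integer matrix of total depth (NA where genotype is missing).
#' @param lines Character vector of panel line ids (column order of the
#'   matrices).
#' @return An object of class `"variant_panel"`.
#' @export
variant_panel <- function(variants, gt, ad, dp, lines) {
  ann_cols <- c("MQ", "QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum")
  need <- c("contig", "pos", "ref", "alt", ann_cols)
  if (!all(need %in% names(variants)))
    stop("variants must have columns: ", paste(need, collapse = ", "))
  n <- nrow(variants)
  for (m in list(gt, ad, dp))
    if (!is.matrix(m) || nrow(m) != n || ncol(m) != length(lines))
      stop("gt/ad/dp must be variants x lines matrices")
  if (any(variants$pos < 1)) stop("positions must be >= 1")
  if (any(variants$ref == variants$alt)) stop("ref must differ from alt")
  key <- paste(variants$contig, variants$pos, variants$alt)
  if (anyDuplicated(key))
    stop("duplicate (contig, pos, alt) record after splitting")
  ok <- gt %in% c("hom_ref", "het", "hom_alt", "missing")
  if (!all(ok)) stop("invalid genotype code(s): ",
                     paste(unique(gt[!ok]), collapse = ", "))
  if (any(ad < 0, na.rm = TRUE) || any(dp < 0, na.rm = TRUE))
    stop("read counts must be non-negative")
  colnames(gt) <- colnames(ad) <- colnames(dp) <- lines
  rownames(variants) <- NULL
  structure(list(variants = variants, gt = gt, ad = ad, dp = dp,
                 lines = as.character(lines)),
            class = "variant_panel")
}

#' @export
print.variant_panel <- function(x, ...) {
  cat(sprintf("variant_panel: %d records x %d lines on contig(s) %s\n",
              nrow(x$variants), length(x$lines),
              paste(unique(x$variants$contig), collapse = ", ")))
  invisible(x)
}

#' Number of variant records in a panel
#' @param panel A [variant_panel()].
#' @export
n_variants <- function(panel) nrow(panel$variants)

.vcf_ann_keys <- c("MQ", "QD", "FS", "SOR", "MQRankSum", "ReadPosRankSum")

#' Read a multi-sample VCF into a variant panel
#'
#' Supports the restricted VCF 4.2 dialect produced by joint short-variant
#' calling: INFO keys MQ, QD, FS, SOR, MQRankSum, ReadPosRankSum (any may be
#' absent at a site) and FORMAT `GT:AD:DP`. Multiallelic rows are split into
#' one record per alternate allele; the per-allele read support is taken from
#' the allele's AD entry and site-level annotations are copied to every child
#' record. Genotypes are normalised to four states by counting copies of the
#' record's allele (0 copies = hom_ref, 1 = het, 2 = hom_alt, uncalled =
#' missing).
#'
#' @param path Path to an uncompressed VCF file.
#' @param panel_line_ids Expected sample names; a mismatch with the VCF header
#'   is a configuration error. `NULL` accepts whatever the header declares.
#' @param analyzed_contigs Contigs retained in the returned panel. Records on
#'   `extra_contigs` (chromosome 4 by default) are parsed and returned in the
#'   `"extra"` attribute rather than discarded; records on any other contig are
#'   dropped with a warning.
#' @param extra_contigs Contigs routed to the `"extra"` attribute.
#' @return A [variant_panel()] restricted to `analyzed_contigs`, with
#'   attribute `"extra"` holding a second panel for `extra_contigs` (NULL if
#'   none were present).
#' @export
read_vcf <- function(path, panel_line_ids = NULL,
                     analyzed_contigs = c("2L", "2R", "3L", "3R", "X"),
                     extra_contigs = "4") {
  raw <- readLines(path)
  n_header <- sum(startsWith(raw, "#"))
  vcf <- suppressWarnings(vcfR::read.vcfR(path, verbose = FALSE))
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  samples <- colnames(vcf@gt)[-1]
  if (!is.null(panel_line_ids)) {
    if (!identical(sort(samples), sort(as.character(panel_line_ids))))
      stop("configuration error: VCF samples do not match panel line ids")
    samples <- as.character(panel_line_ids)
  }
  contig <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  # positions must be sorted within each contig, in file order
  for (ctg in unique(contig)) {
    p <- pos[contig == ctg]
    if (is.unsorted(p)) {
      row <- which(contig == ctg)[which(diff(p) < 0)[1] + 1L]
      stop("parse error: non-monotone position on contig ", ctg,
           " at file line ", n_header + row)
    }
  }
  ann <- sapply(.vcf_ann_keys, function(k)
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = k))),
    simplify = FALSE)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  ad_raw <- vcfR::extract.gt(vcf, element = "AD")
  dp_raw <- suppressWarnings(
    matrix(as.integer(vcfR::extract.gt(vcf, element = "DP")),
           nrow = nrow(fix)))
  if (is.null(dim(gt_raw))) {
    gt_raw <- matrix(gt_raw, nrow = nrow(fix))
    ad_raw <- matrix(ad_raw, nrow = nrow(fix))
  }
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  row_idx <- rep(seq_along(n_alt), n_alt)
  alt_k <- sequence(n_alt)          # which ALT within the source row

  a1 <- matrix(sub("[/|].*", "", gt_raw), nrow = nrow(gt_raw))
  a2 <- matrix(sub(".*[/|]", "", gt_raw), nrow = nrow(gt_raw))

  n_out <- length(row_idx)
  n_smp <- length(samples)
  gt <- matrix("missing", n_out, n_smp)
  ad <- matrix(NA_integer_, n_out, n_smp)
  dp <- matrix(NA_integer_, n_out, n_smp)
  for (j in seq_len(n_smp)) {
    kchr <- as.character(alt_k)
    a1j <- a1[row_idx, j]; a2j <- a2[row_idx, j]
    called <- !is.na(a1j) & a1j != "." & a2j != "."
    copies <- (a1j == kchr) + (a2j == kchr)
    g <- ifelse(!called, "missing",
                ifelse(copies == 2, "hom_alt",
                       ifelse(copies == 1, "het", "hom_ref")))
    gt[, j] <- g
    dp[, j] <- ifelse(called, dp_raw[row_idx, j], NA_integer_)
  }
  # per-sample AD: ad_raw[row, sample] is "ref,alt1,alt2,..."; take entry k+1
  ad_mat_split <- apply(ad_raw, 2, function(col)
    strsplit(ifelse(is.na(col), "", col), ",", fixed = TRUE),
    simplify = FALSE)
  for (j in seq_len(n_smp)) {
    spl <- ad_mat_split[[j]]
    vals <- vapply(seq_len(n_out), function(i) {
      parts <- spl[[row_idx[i]]]
      k <- alt_k[i] + 1L
      if (length(parts) < k) return(NA_integer_)
      suppressWarnings(as.integer(parts[k]))
    }, NA_integer_)
    ad[, j] <- ifelse(gt[, j] == "missing", NA_integer_, vals)
  }
  variants <- data.frame(contig = contig[row_idx], pos = pos[row_idx],
                         ref = fix[row_idx, "REF"],
                         alt = unlist(alts),
                         stringsAsFactors = FALSE)
  for (k in .vcf_ann_keys) variants[[k]] <- ann[[k]][row_idx]

  keep <- variants$contig %in% analyzed_contigs
  extra <- variants$contig %in% extra_contigs
  other <- !keep & !extra
  if (any(other))
    warning("dropping ", sum(other), " record(s) on unanalysed contig(s): ",
            paste(unique(variants$contig[other]), collapse = ", "))
  build <- function(sel) {
    if (!any(sel)) return(NULL)
    variant_panel(variants[sel, , drop = FALSE],
                  gt[sel, , drop = FALSE], ad[sel, , drop = FALSE],
                  dp[sel, , drop = FALSE], samples)
  }
  main <- build(keep)
  if (is.null(main))
    main <- variant_panel(variants[0, , drop = FALSE],
                          gt[0, , drop = FALSE], ad[0, , drop = FALSE],
                          dp[0, , drop = FALSE], samples)
  attr(main, "extra") <- build(extra)
  main
}

#' Write a variant panel as a multi-sample VCF 4.2 file
#'
#' Each record becomes one biallelic VCF row with the site annotations in INFO
#' (absent annotations omitted) and FORMAT `GT:AD:DP`. Records are written
#' sorted by contig then position.
#'
#' @param panel A [variant_panel()].
#' @param path Output path.
#' @param contig_lengths Optional named vector for `##contig` header lines.
#' @export
write_vcf <- function(panel, path, contig_lengths = NULL) {
  v <- panel$variants
  ord <- order(v$contig, v$pos)
  v <- v[ord, , drop = FALSE]
  gt <- panel$gt[ord, , drop = FALSE]
  ad <- panel$ad[ord, , drop = FALSE]
  dp <- panel$dp[ord, , drop = FALSE]

  hdr <- c("##fileformat=VCFv4.2",
           if (!is.null(contig_lengths))
             sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                     as.integer(contig_lengths)),
           sprintf("##INFO=<ID=%s,Number=1,Type=Float,Description=\"%s\">",
                   .vcf_ann_keys, .vcf_ann_keys),
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$lines), collapse = "\t"))
  n <- nrow(v)
  info <- vapply(seq_len(n), function(i) {
    vals <- unlist(v[i, .vcf_ann_keys])
    pres <- !is.na(vals)
    if (!any(pres)) return(".")
    paste(paste0(.vcf_ann_keys[pres], "=",
                 vapply(vals[pres], format_num, "")), collapse = ";")
  }, "")
  gt_code <- c(hom_ref = "0/0", het = "0/1", hom_alt = "1/1", missing = "./.")
  smp <- matrix("", n, length(panel$lines))
  for (j in seq_along(panel$lines)) {
    g <- gt[, j]
    miss <- g == "missing"
    refd <- dp[, j] - ad[, j]
    cell <- paste0(gt_code[g], ":", refd, ",", ad[, j], ":", dp[, j])
    cell[miss] <- "./.:.,.:."
    smp[, j] <- cell
  }
  body <- paste(v$contig, v$pos, ".", v$ref, v$alt, ".", ".", info,
                "GT:AD:DP",
                apply(smp, 1, paste, collapse = "\t"), sep = "\t")
  if (n == 0) body <- character(0)
  writeLines(c(hdr, body), path)
  invisible(path)
}
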