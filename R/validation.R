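# Post-ranking validation: the summary-data-based Mendelian randomization
# (SMR) statistic for integrating GWAS and eQTL summary statistics, and
# the blood tissue-specificity filter applied to novel candidates.

#' SMR statistic for one SNP
#'
#' Summary-data-based Mendelian randomization treats a SNP as an
#' instrument to test whether a gene's expression and a trait share a
#' causal variant.  With z-scores \eqn{z_G = b_G / se_G} (GWAS) and
#' \eqn{z_E = b_E / se_E} (eQTL), the effect of expression on the trait is
#' \eqn{b_{SMR} = b_G / b_E} and the test statistic is
#' \deqn{T_{SMR} = \frac{z_G^2 z_E^2}{z_G^2 + z_E^2},}
#' compared against a chi-square distribution with one degree of freedom.
#' \eqn{T_{SMR} \le \min(z_G^2, z_E^2)}: the instrument is only as strong
#' as its weaker arm.
#'
#' @param gwas,eqtl One-row data frames (or lists) with elements `beta` and
#'   `se` (and optionally `snp_id`); `se` must be positive and the eQTL
#'   `beta` nonzero.
#' @return A one-row tibble with columns `snp_id`, `b_smr`, `t_smr`,
#'   `p_smr`.
#' @examples
#' smr_statistic(list(beta = 0.2, se = 0.1), list(beta = 0.4, se = 0.2))
#' @export
smr_statistic <- function(gwas, eqtl) {
  b_g <- as.numeric(gwas$beta)
  se_g <- as.numeric(gwas$se)
  b_e <- as.numeric(eqtl$beta)
  se_e <- as.numeric(eqtl$se)
  stopifnot(length(b_g) == 1, length(b_e) == 1)
  if (se_g <= 0 || se_e <= 0) {
    abort("Standard errors must be strictly positive")
  }
  if (b_e == 0) {
    abort("eQTL effect is zero: b_smr undefined")
  }
  z_g2 <- (b_g / se_g)^2
  z_e2 <- (b_e / se_e)^2
  t_smr <- z_g2 * z_e2 / (z_g2 + z_e2)
  snp <- gwas$snp_id %||% eqtl$snp_id %||% NA_character_
  tibble::tibble(
    snp_id = as.character(snp),
    b_smr = b_g / b_e,
    t_smr = t_smr,
    p_smr = pchisq(t_smr, df = 1, lower.tail = FALSE)
  )
}

#' SMR scan over a locus
#'
#' Joins per-SNP GWAS and eQTL summary statistics on `snp_id`, computes the
#' SMR statistic for every shared SNP, and flags SNPs whose SMR p-value
#' falls below `p_threshold`.  When a SNP carries several GWAS entries
#' (e.g. from two GWAS datasets), the one with the smaller GWAS p-value
#' (larger `|z|`) is kept.  SNPs present in only one table are dropped,
#' with a message reporting how many.
#'
#' @param gwas,eqtl Data frames with columns `snp_id`, `beta`, `se`.
#' @param p_threshold Significance threshold on the SMR p-value.
#'   Default 0.05.
#' @return A tibble with one row per shared SNP: `snp_id`, `b_smr`,
#'   `t_smr`, `p_smr`, `pass`.
#' @export
locus_scan <- function(gwas, eqtl, p_threshold = 0.05) {
  need <- c("snp_id", "beta", "se")
  stopifnot(is.data.frame(gwas), all(need %in% names(gwas)),
            is.data.frame(eqtl), all(need %in% names(eqtl)))
  gwas <- dplyr::slice_max(
    dplyr::group_by(tibble::as_tibble(gwas), .data$snp_id),
    abs(.data$beta / .data$se), n = 1, with_ties = FALSE
  )
  gwas <- dplyr::ungroup(gwas)
  eqtl <- dplyr::distinct(tibble::as_tibble(eqtl), .data$snp_id,
                          .keep_all = TRUE)
  shared <- intersect(gwas$snp_id, eqtl$snp_id)
  dropped <- length(unique(gwas$snp_id)) + length(unique(eqtl$snp_id)) -
    2L * length(shared)
  if (length(shared) == 0) {
    abort("No SNP shared between the GWAS and eQTL tables")
  }
  if (dropped > 0) {
    inform(paste0(dropped, " SNP(s) present in only one table were dropped"))
  }
  g <- gwas[match(shared, gwas$snp_id), ]
  e <- eqtl[match(shared, eqtl$snp_id), ]
  out <- purrr::map2(
    split(g, seq_len(nrow(g))), split(e, seq_len(nrow(e))),
    smr_statistic
  )
  out <- dplyr::bind_rows(out)
  out$snp_id <- shared
  out$pass <- out$p_smr < p_threshold
  out
}

#' Load the packaged blood-specific candidate table
#'
#' The packaged table of novel AD-candidate proteins whose expression is
#' tissue-specific to blood, with accession, protein name and gene symbol.
#'
#' @return A tibble with columns `accession`, `protein_name`, `gene`,
#'   `tissue`.
#' @export
load_blood_reference <- function() {
  path <- system.file("extdata", "blood_specific_proteins.tsv",
                      package = "ibds", mustWork = TRUE)
  readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                  progress = FALSE)
}

#' Filter candidates to blood-specific proteins
#'
#' Keeps the candidate accessions whose tissue annotation matches the
#' blood label (case-insensitively).  Candidates without an annotation are
#' excluded — absence of evidence of blood specificity drops a candidate.
#'
#' @param candidates Character vector of candidate accessions.
#' @param annotations Either a data frame with columns `accession`,
#'   `tissue` (e.g. [load_blood_reference()]) or a character vector of
#'   tissue labels named by accession.
#' @param tissue Tissue label to keep. Default `"blood"`.
#' @return Character vector: the blood-specific candidates, in candidate
#'   order.
#' @export
blood_specific_filter <- function(candidates, annotations, tissue = "blood") {
  candidates <- as.character(candidates)
  if (is.data.frame(annotations)) {
    stopifnot(all(c("accession", "tissue") %in% names(annotations)))
    ann <- setNames(as.character(annotations$tissue),
                    as.character(annotations$accession))
  } else {
    ann <- annotations
    if (is.null(names(ann))) {
      abort("annotations vector must be named by accession")
    }
  }
  label <- tolower(ann[candidates])
  candidates[!is.na(label) & label == tolower(tissue)]
}
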