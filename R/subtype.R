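#' Molecular subtype labels
#'
#' The five immunohistochemistry-derived molecular subtypes used throughout
#' the package, and the four coarse hormone-receptor/HER2 groups they
#' collapse into.
#'
#' @return Character vector of valid labels.
#' @export
subtype_levels <- function() {
  c("luminal_A", "luminal_B_HER2neg", "luminal_B_HER2pos",
    "HER2pos", "triple_negative")
}

#' @rdname subtype_levels
#' @export
coarse_subtype_levels <- function() {
  c("HRpos_HER2neg", "HRpos_HER2pos", "HRneg_HER2pos", "TNBC")
}

#' Derive the molecular subtype from IHC receptor status
#'
#' Implements the surrogate St Gallen-style subtype rules used in clinical
#' breast-cancer pathology: luminal A requires ER+ and PR+, HER2- and low
#' Ki67 (<= 14\%); luminal B/HER2- requires ER or PR positivity, HER2- and
#' high Ki67 (> 14\%); luminal B/HER2+ is hormone-receptor positive and
#' HER2+; HER2+ (non-luminal) is ER-, PR- and HER2+; triple-negative is
#' negative for all three markers.  Ki67 only matters for HER2-negative,
#' hormone-receptor-positive disease; when it is required but missing the
#' call is refused rather than silently defaulted.
#'
#' @param er_positive,pr_positive,her2_positive Logical vectors (recycled to
#'   a common length).
#' @param ki67_fraction Numeric vector of Ki67 positive fractions in
#'   \[0, 1\]; may be `NA` where the rules do not need it.
#' @param ki67_low_max Upper bound of "low" Ki67 (inclusive), default 0.14.
#' @return Character vector of subtype labels (see [subtype_levels()]).
#' @examples
#' derive_subtype(TRUE, TRUE, FALSE, 0.10)   # luminal_A
#' derive_subtype(FALSE, FALSE, FALSE, NA)   # triple_negative
#' @export
derive_subtype <- function(er_positive, pr_positive, her2_positive,
                           ki67_fraction = NA_real_, ki67_low_max = 0.14) {
  n <- max(length(er_positive), length(pr_positive), length(her2_positive),
           length(ki67_fraction))
  er <- rep_len(as.logical(er_positive), n)
  pr <- rep_len(as.logical(pr_positive), n)
  her2 <- rep_len(as.logical(her2_positive), n)
  ki67 <- rep_len(as.numeric(ki67_fraction), n)
  if (anyNA(er) || anyNA(pr) || anyNA(her2)) {
    stop("derive_subtype: ER/PR/HER2 status must be defined (non-NA)")
  }
  if (any(!is.na(ki67) & (ki67 < 0 | ki67 > 1))) {
    stop("derive_subtype: ki67_fraction must lie in [0, 1]")
  }
  hr <- er | pr
  out <- character(n)
  out[!hr & her2] <- "HER2pos"
  out[!hr & !her2] <- "triple_negative"
  out[hr & her2] <- "luminal_B_HER2pos"
  # HR+/HER2-: Ki67 decides; ER+ and PR+ with low Ki67 is luminal A,
  # anything else HR+/HER2- is luminal B/HER2- (incl. single-receptor
  # positivity with low Ki67, which fails the ER+ and PR+ requirement).
  need <- hr & !her2
  if (any(need & is.na(ki67))) {
    bad <- which(need & is.na(ki67))
    stop(sprintf(
      "derive_subtype: subtype undeterminable without Ki67 for HR+/HER2- case(s) at position(s) %s",
      paste(bad, collapse = ", ")))
  }
  low <- !is.na(ki67) & ki67 <= ki67_low_max
  out[need & er & pr & low] <- "luminal_A"
  out[need & !(er & pr & low)] <- "luminal_B_HER2neg"
  out
}

#' Collapse molecular subtypes to coarse HR/HER2 groups
#'
#' @param subtype Character vector of labels from [subtype_levels()].
#' @return Character vector of coarse labels (see [coarse_subtype_levels()]).
#' @export
coarse_subtype <- function(subtype) {
  map <- c(luminal_A = "HRpos_HER2neg",
           luminal_B_HER2neg = "HRpos_HER2neg",
           luminal_B_HER2pos = "HRpos_HER2pos",
           HER2pos = "HRneg_HER2pos",
           triple_negative = "TNBC")
  bad <- setdiff(unique(subtype), names(map))
  if (length(bad) > 0) {
    stop("coarse_subtype: unknown subtype label(s): ", paste(bad, collapse = ", "))
  }
  unname(map[subtype])
}
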