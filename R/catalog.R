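#' Transporter substrate catalog
#'
#' Substrate lists and affinity ranks of the three enterocyte carriers
#' involved in levodopa transport, plus the renal and blood-brain
#' barrier carriers of the extended (kidney/brain) model:
#' \itemize{
#'   \item luminal antiporter (system b0,+-like): dibasic and neutral
#'     amino acids plus levodopa; cystine has the highest and ornithine
#'     the lowest affinity;
#'   \item basolateral antiporter (LAT2-like): neutral amino acids plus
#'     levodopa (the trans-stimulation route);
#'   \item basolateral uniporter (TAT1-like): aromatic amino acids plus
#'     levodopa; carries four fifths of basolateral levodopa efflux,
#'     the antiporter one fifth.
#' }
#' Rank 1 is the highest affinity; the rank order is the information
#' carried by the catalog and is mapped to geometric carrier-share
#' weights `2^-rank` (see [competition_share()]). The acidic amino
#' acids (aspartate, glutamate) are substrates of none of these
#' carriers.
#'
#' @param split_fraction_uniporter fraction of basolateral levodopa
#'   efflux routed through the uniporter (enforced as a linear coupling
#'   in every flux solution).
#' @return object of class `transporter_catalog`.
#' @export
transporter_catalog <- function(split_fraction_uniporter = 4 / 5) {
  if (split_fraction_uniporter <= 0 || split_fraction_uniporter >= 1)
    stop("split_fraction_uniporter must lie in (0, 1)", call. = FALSE)
  lum <- c(cystine = 1, arg = 2, lys = 3, leu = 4, phe = 5, met = 6,
           ile = 7, val = 8, trp = 9, his = 10, tyr = 11, ala = 12,
           cys = 13, gln = 14, pro = 15, thr = 16, ser = 17, asn = 18,
           gly = 19, ornithine = 20)
  bl_anti <- c(leu = 1, phe = 2, ile = 3, val = 4, met = 5, tyr = 6,
               trp = 7, his = 8, gln = 9, ala = 10, ser = 11, thr = 12,
               asn = 13)
  uni <- c("phe", "tyr", "trp")
  renal <- c(ser = 1, thr = 2, asn = 3, gly = 4, gln = 5, ala = 6,
             cys = 7, pro = 8)
  brain <- c(phe = 1, trp = 2, leu = 3, tyr = 4, ile = 5, met = 6,
             val = 7, his = 8)
  structure(list(
    luminal_antiporter = lum,
    luminal_levodopa_rank = 11,
    basolateral_antiporter = bl_anti,
    basolateral_levodopa_rank = 6,
    basolateral_uniporter = uni,
    renal_carrier = renal,
    renal_levodopa_rank = 4,
    brain_carrier = brain,
    brain_levodopa_rank = 1,
    split_fraction_uniporter = split_fraction_uniporter,
    # carrier gene annotations (metadata only)
    genes = c(luminal_antiporter = "11067-6591",
              basolateral_uniporter = "117247",
              basolateral_antiporter = "23428-6520")
  ), class = "transporter_catalog")
}

#' Levodopa share of a shared carrier
#'
#' Affinity-weighted capacity share: with geometric weights
#' `w = 2^-rank`, levodopa's share of the carrier is
#' `w_L q_L / (w_L q_L + sum_i w_i q_i)` where `q` are the competing
#' substrate amounts. With no competitors the full capacity goes to
#' levodopa; a saturating amount of the highest-affinity substrate
#' (cystine on the luminal carrier) drives the share to zero; the share
#' is non-increasing in every competitor amount.
#'
#' @param levodopa_amount levodopa amount (mmol or any common unit).
#' @param aa_amounts named vector of competing amino-acid amounts in the
#'   same unit; names from `AA_SPECIES`. Species that are not carrier
#'   substrates are ignored.
#' @param ranks named rank vector of the carrier's substrates.
#' @param levodopa_rank levodopa's rank on the carrier.
#' @return share in [0, 1].
#' @export
competition_share <- function(levodopa_amount, aa_amounts, ranks,
                              levodopa_rank) {
  if (length(aa_amounts) && is.null(names(aa_amounts)))
    stop("aa_amounts must be named", call. = FALSE)
  if (any(aa_amounts < 0) || levodopa_amount < 0)
    stop("amounts must be nonnegative", call. = FALSE)
  unknown <- setdiff(names(aa_amounts), AA_SPECIES)
  if (length(unknown))
    stop("unknown species: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  sub <- intersect(names(aa_amounts), names(ranks))
  wl <- 2^(-levodopa_rank) * levodopa_amount
  wa <- sum(2^(-ranks[sub]) * aa_amounts[sub])
  if (wl + wa <= 0) return(1)   # sole (or no) substrate: full capacity
  wl / (wl + wa)
}
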