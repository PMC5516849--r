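#' Amino-acid species of the transporter catalog
#'
#' The 20 proteinogenic amino acids plus cystine and ornithine,
#' by three-letter code.
#' @export
AA_SPECIES <- c("ala", "arg", "asn", "asp", "cys", "gln", "glu", "gly",
                "his", "ile", "leu", "lys", "met", "phe", "pro", "ser",
                "thr", "trp", "tyr", "val", "cystine", "ornithine")

#' Amino-acid molecular weights, mg/mmol
#' @export
AA_MW <- c(ala = 89.1, arg = 174.2, asn = 132.1, asp = 133.1,
           cys = 121.2, gln = 146.1, glu = 147.1, gly = 75.1,
           his = 155.2, ile = 131.2, leu = 131.2, lys = 146.2,
           met = 149.2, phe = 165.2, pro = 115.1, ser = 105.1,
           thr = 119.1, trp = 204.2, tyr = 181.2, val = 117.1,
           cystine = 240.3, ornithine = 132.2)

SI_SEGMENTS <- c("duodenum", "jejunum1", "jejunum2",
                 "ileum1", "ileum2", "ileum3", "ileum4")

LUMINAL_COMPARTMENTS <- c("stomach", SI_SEGMENTS, "colon")

PBPK_ORGANS <- c("heart", "brain", "muscle", "adipose", "skin", "bone",
                 "kidney", "liver", "spleen", "pancreas", "rest_of_body")

#' Molecular weight of levodopa, mg/mmol
#' @export
LEVODOPA_MW <- 197.19
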