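# Published reference tables from the Barrett's epithelial carcinogenesis
# (BEC) model: replicate karyotypes of the 20-week cultures grown a further
# 14 weeks with/without acid+bile-salt exposure, and the breakpoint-region
# genes on 2p22 / 10q22 / 16q22 with their reported BEC40W/BEC20W fold
# changes (Hg19 coordinates).

#' Replicate karyotypes of the BEC model cultures
#'
#' Six replicate wells of 20-week Barrett's epithelial cells grown 14 more
#' weeks either without (`unexposed`) or with (`exposed`) further acidified
#' bile-salt exposure, as ISCN strings.  Four of the six exposed replicates
#' carry the three-way translocation t(2;10;16) together with a doubled
#' chromosome-20 gain; the strings print the third translocation band
#' variably as q22 or q21, which is why [match_aberration()] exposes band
#' resolutions.
#'
#' Strings are kept verbatim, including incidental spacing around some
#' `+20` tokens; [parse_karyotype()] ignores whitespace.
#'
#' @return data.frame with columns `well`, `unexposed`, `exposed`.
#' @export
bec_karyotypes <- function() {
  unexp <- "47,XY,add(4)(p16.1),add(7)(p22),i(8)(q10),+20"
  data.frame(
    well = 1:6,
    unexposed = c(unexp,
                  "47,XY,add(4)(p16.1),add(7)(p22),i(8)(q10), + 20",
                  unexp, unexp, unexp, unexp),
    exposed = c(
      "48,XY,i(8)(q10),t(2;10;16)(p22;q22;q22),+20,+20",
      "47,XY,add(7)(p22),i(8)(q10),+20",
      "48,XY,i(8)(q10),t(2;10;16)(p22;q22;q21), + 20,+20",
      "47,XY,add(7)(p22),i(8)(q10),+20",
      "48,XY,i(8)(q10),t(2;10;16)(p22;q22;q21), + 20, + 20",
      "48,XY,i(8)(q10),t(2;10;16)(p22;q22;q21),+20,+20"),
    stringsAsFactors = FALSE
  )
}

#' Breakpoint-region genes with reported fold changes
#'
#' The genes inside the 2p22, 10q22, and 16q22 breakpoint windows reported
#' as altered more than twofold (p < 0.025) between BEC40W and BEC20W
#' cells, with their published Hg19 coordinates and signed
#' (BEC40W/BEC20W) fold changes.  14 genes on 2p22, 10 on 10q22, 16 on
#' 16q22.  The PLA2G15 coordinates are the Hg19 RefSeq interval (the
#' published table lists the gene but its coordinate row is reconstructed).
#'
#' @return data.frame with columns `gene_id`, `window`, `chrom`, `start`,
#'   `end`, `reported_fc`.
#' @export
breakpoint_genes <- function() {
  tab <- rbind(
    # 2p22 (chr2)
    c("FNDC4",    "2p22", "2", 27714749, 27718126,   2.2),
    c("GCKR",     "2p22", "2", 27719705, 27746550, -81.4),
    c("RBKS",     "2p22", "2", 28004265, 28561767,  20.6),
    c("FOSL2",    "2p22", "2", 28615778, 28637516,   2.9),
    c("SPDYA",    "2p22", "2", 29033699, 29093175,   2.7),
    c("FAM179A",  "2p22", "2", 29204163, 29275096,  50.6),
    c("CLIP4",    "2p22", "2", 29338307, 29406679,   2.0),
    c("YPEL5",    "2p22", "2", 30369749, 30383399,   2.9),
    c("LBH",      "2p22", "2", 30454396, 30482899,   2.6),
    c("GALNT14",  "2p22", "2", 31133332, 31361571, -20.6),
    c("CAPN14",   "2p22", "2", 31395921, 31440411,  -6.6),
    c("XDH",      "2p22", "2", 31557187, 31637611,  -4.8),
    c("NLRC4",    "2p22", "2", 32449517, 32490812,  -3.2),
    c("RASGRP3",  "2p22", "2", 33661415, 33789798,   2.9),
    # 10q22 (chr10)
    c("MBL1P",    "10q22", "10", 81664653, 81691557, -52.5),
    c("LDB3",     "10q22", "10", 88428205, 88495824, -39.2),
    c("MMRN2",    "10q22", "10", 88695297, 88717425,   4.9),
    c("SNCG",     "10q22", "10", 88718287, 88723017,  15.9),
    c("AGAP11",   "10q22", "10", 88728187, 88769960,   6.9),
    c("FAM25A",   "10q22", "10", 88780045, 88784487, 430.4),
    c("FAM22D",   "10q22", "10", 89117476, 89130452,   3.7),
    c("PAPSS2",   "10q22", "10", 89419475, 89507462,  -2.7),
    c("ANKRD22",  "10q22", "10", 90562486, 90611732, -17.9),
    c("STAMBPL1", "10q22", "10", 90640025, 90683244, -20.0),
    # 16q22 (chr16)
    c("RRAD",     "16q22", "16", 66955581, 66959439,   2.5),
    c("CES2",     "16q22", "16", 66968346, 66978994,   2.4),
    c("CES4A",    "16q22", "16", 67022491, 67043659, -20.3),
    c("B3GNT9",   "16q22", "16", 67143914, 67184902,   2.5),
    c("TRADD",    "16q22", "16", 67188088, 67193812,   3.2),
    c("HSF4",     "16q22", "16", 67193890, 67203848,   6.7),
    c("ELMO3",    "16q22", "16", 67233027, 67237927,   3.3),
    c("LRRC29",   "16q22", "16", 67241041, 67260901,  56.6),
    c("FHOD1",    "16q22", "16", 67263291, 67281425,  -2.8),
    c("SLC9A5",   "16q22", "16", 67282854, 67306094,   3.4),
    c("HSD11B2",  "16q22", "16", 67465035, 67471454,   3.4),
    c("ACD",      "16q22", "16", 67679029, 67694718,   3.9),
    c("PARD6A",   "16q22", "16", 67694850, 67696681, -64.3),
    c("SLC12A4",  "16q22", "16", 67973786, 68002597,   2.7),
    c("ESRP2",    "16q22", "16", 68119268, 68270136,   2.8),
    c("PLA2G15",  "16q22", "16", 68279112, 68305179,   2.1)
  )
  data.frame(gene_id = tab[, 1], window = tab[, 2], chrom = tab[, 3],
             start = as.numeric(tab[, 4]), end = as.numeric(tab[, 5]),
             reported_fc = as.numeric(tab[, 6]), stringsAsFactors = FALSE)
}
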