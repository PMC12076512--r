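# Physicochemical profiling: QED drug-likeness, clogP/TPSA and the classic
# hydrogen-bonding counts, plus the per-molecule property table used for
# library characterization.

# Published asymmetric double sigmoid (ADS) parameter sets of the QED
# desirability functions, one row per descriptor (a, b, c, d, e, f, dmax),
# and the mean-weighting scheme.
QED_ADS <- list(
  MW     = c(2.817065973, 392.5754953, 290.7489764, 2.419764353, 49.22325677, 65.37051707, 104.9805561),
  ALOGP  = c(3.172690585, 137.8624751, 2.534937431, 4.581497897, 0.822739154, 0.576295591, 131.3186604),
  HBA    = c(2.948620388, 160.4605972, 3.615294657, 4.435986202, 0.290141953, 1.300669958, 148.7763046),
  HBD    = c(1.618662227, 1010.051101, 0.985094388, 1e-09, 0.713820843, 0.920922555, 258.1632616),
  PSA    = c(1.876861559, 125.2232657, 62.90773554, 87.83366614, 12.01999824, 28.51324732, 104.5686167),
  ROTB   = c(0.01, 272.4121427, 2.55837997, 1.565547684, 1.271567166, 2.758063707, 105.4420403),
  AROM   = c(3.21778897, 957.7374108, 2.274627939, 1e-09, 1.317690384, 0.375760881, 312.337261),
  ALERTS = c(0.01, 1199.094025, -0.09002883, 1e-09, 0.185904477, 0.875193782, 417.725314)
)
QED_WEIGHTS <- c(MW = 0.66, ALOGP = 0.46, HBA = 0.05, HBD = 0.61,
                 PSA = 0.06, ROTB = 0.65, AROM = 0.48, ALERTS = 0.95)

# compact structural-alert subset (full published alert list not shipped;
# the ALERTS term is an approximation, see the methods vignette)
QED_ALERT_SMARTS <- c(
  "[N+](=O)[O-]",          # nitro
  "N=[N+]=[N-]",           # azide
  "C(=O)Cl",               # acid chloride
  "S(=O)(=O)Cl",           # sulfonyl chloride
  "N=C=O",                 # isocyanate
  "N=C=S",                 # isothiocyanate
  "C1OC1",                 # epoxide
  "C1NC1",                 # aziridine
  "N-N=O",                 # nitrosamine
  "SS",                    # disulfide
  "C(=O)C(=O)",            # 1,2-dicarbonyl
  "[CH]=O"                 # aldehyde
)

ads_desirability <- function(x, p) {
  a <- p[1]; b <- p[2]; cc <- p[3]; d <- p[4]; e <- p[5]; f <- p[6]; dmax <- p[7]
  val <- a + b / (1 + exp(-(x - cc + d / 2) / e)) *
    (1 - 1 / (1 + exp(-(x - cc - d / 2) / f)))
  val / dmax
}

#' Quantitative estimate of drug-likeness (QED)
#'
#' Weighted geometric mean of the published desirability functions over
#' eight descriptors (MW, clogP, HBA, HBD, TPSA, rotatable bonds, aromatic
#' rings, structural alerts). clogP and TPSA come from the OpenBabel
#' descriptor models, and the structural-alerts term counts a compact alert
#' subset, so values can differ slightly from other toolkits.
#'
#' @param smiles character vector of valid SMILES.
#' @return numeric vector of QED scores in \[0, 1\].
#' @export
qed_score <- function(smiles) {
  props <- property_profile(smiles)
  props$qed
}

#' Per-molecule property table
#'
#' QED, clogP, TPSA, hydrogen-bond acceptor/donor counts, molecular weight,
#' rotatable bonds, aromatic ring count and largest ring size, one row per
#' molecule. Molecules whose descriptors cannot be computed are flagged in
#' `descriptor_ok` rather than dropped. The attached `"summary"` attribute
#' holds median and quartiles per property.
#'
#' @param smiles character vector of valid SMILES.
#' @return tibble with one row per molecule.
#' @export
property_profile <- function(smiles) {
  stopifnot(length(smiles) > 0)
  ok <- smiles_valid(smiles)
  rows <- vector("list", length(smiles))
  good <- which(ok)
  if (length(good) > 0) {
    gd <- graph_descriptors(smiles[good])
    pr <- ob_properties(smiles[good])
    refs <- ob_mol_refs(smiles[good])
    alerts <- rep(0, length(good))
    for (al in QED_ALERT_SMARTS) {
      cnt <- try(ob_smarts_count(refs, al), silent = TRUE)
      if (!inherits(cnt, "try-error")) alerts <- alerts + as.numeric(cnt > 0)
    }
    dvals <- cbind(
      MW = ads_desirability(gd$mw, QED_ADS$MW),
      ALOGP = ads_desirability(pr$clogp, QED_ADS$ALOGP),
      HBA = ads_desirability(gd$hba, QED_ADS$HBA),
      HBD = ads_desirability(gd$hbd, QED_ADS$HBD),
      PSA = ads_desirability(pr$tpsa, QED_ADS$PSA),
      ROTB = ads_desirability(gd$rotb, QED_ADS$ROTB),
      AROM = ads_desirability(gd$arom_rings, QED_ADS$AROM),
      ALERTS = ads_desirability(alerts, QED_ADS$ALERTS)
    )
    w <- QED_WEIGHTS[colnames(dvals)]
    qed <- exp(as.numeric(log(pmax(dvals, 1e-12)) %*% w) / sum(w))
    for (i in seq_along(good)) {
      rows[[good[i]]] <- tibble::tibble(
        smiles = smiles[good[i]], descriptor_ok = TRUE,
        qed = qed[i], clogp = pr$clogp[i], tpsa = pr$tpsa[i],
        hba = gd$hba[i], hbd = gd$hbd[i], mw = gd$mw[i],
        rotb = gd$rotb[i], arom_rings = gd$arom_rings[i],
        max_ring = gd$max_ring[i]
      )
    }
  }
  for (i in which(!ok)) {
    rows[[i]] <- tibble::tibble(
      smiles = smiles[i], descriptor_ok = FALSE,
      qed = NA_real_, clogp = NA_real_, tpsa = NA_real_,
      hba = NA_integer_, hbd = NA_integer_, mw = NA_real_,
      rotb = NA_integer_, arom_rings = NA_integer_, max_ring = NA_integer_
    )
  }
  out <- dplyr::bind_rows(rows)
  num_cols <- c("qed", "clogp", "tpsa", "hba", "hbd", "mw", "rotb")
  summ <- dplyr::bind_rows(lapply(num_cols, function(cn) {
    v <- out[[cn]][out$descriptor_ok]
    tibble::tibble(
      property = cn,
      q1 = stats::quantile(v, 0.25, na.rm = TRUE, names = FALSE),
      median = stats::median(v, na.rm = TRUE),
      q3 = stats::quantile(v, 0.75, na.rm = TRUE, names = FALSE)
    )
  }))
  attr(out, "summary") <- summ
  out
}
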