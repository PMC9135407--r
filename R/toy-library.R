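#' Built-in toy compound library
#'
#' A hand-written 60-entry SMILES library spanning five scaffold families
#' (dibenzocycloheptene tricyclics, phenols, indoles, benzamides/benzoic
#' acids, piperazines/pyridines) plus planted screening liabilities. It is
#' constructed so that every triage operation is exercisable offline:
#' twelve entries are redundant forms (counterion salts, alternative
#' protonation states, or re-ordered SMILES) of other entries, so the 60
#' raw records collapse to 48 unique standardized structures; several
#' structures match packaged PAINS patterns (a para-quinone, a rhodanine,
#' an azo-phenol, a catechol); three pairs share a molecular formula; and
#' one entry is nortriptyline itself for the reference-similarity filter.
#'
#' @return data.frame with columns `compound_id`, `smiles`, `family`, and
#'   `duplicate_of` (`NA`, or the `compound_id` whose structure this entry
#'   duplicates after standardization).
#' @export
toy_library <- function() {
  e <- function(id, smi, fam, dup = NA_character_) {
    data.frame(compound_id = id, smiles = smi, family = fam,
               duplicate_of = dup, stringsAsFactors = FALSE)
  }
  do.call(rbind, list(
    # tricyclics (nortriptyline scaffold family)
    e("E01", "CN(C)CCC=C1c2ccccc2CCc2ccccc21", "tricyclic"),
    e("E02", "CNCCC=C1c2ccccc2CCc2ccccc21", "tricyclic"),   # nortriptyline
    e("E03", "CN(C)CCC=C1c2ccccc2C=Cc2ccccc21", "tricyclic"),
    e("E04", "O=C1c2ccccc2CCc2ccccc21", "tricyclic"),
    e("E05", "CNCCCC1c2ccccc2C=Cc2ccccc21", "tricyclic"),
    e("E06", "CN(C)CCC=C1c2ccccc2COc2ccccc21", "tricyclic"),
    e("E07", "NCCC=C1c2ccccc2CCc2ccccc21", "tricyclic"),
    e("E08", "CN(C)CCC1c2ccccc2CCc2ccccc21", "tricyclic"),
    # phenols
    e("D01", "Cc1ccccc1O", "phenol"),
    e("D02", "Cc1cccc(O)c1", "phenol"),                     # isomer of D01
    e("D03", "Cc1ccc(O)c(O)c1", "phenol"),                  # catechol (PAINS)
    e("D04", "C=CCc1ccc(O)c(OC)c1", "phenol"),
    e("D05", "OCCc1ccc(O)cc1", "phenol"),
    e("D06", "CC(C)(C)c1ccc(O)cc1", "phenol"),
    e("D07", "COc1cccc(O)c1", "phenol"),
    e("D08", "COc1ccc(O)cc1", "phenol"),                    # isomer of D07
    e("D09", "O=Cc1ccccc1O", "phenol"),
    e("D10", "COc1cc(C=O)ccc1O", "phenol"),
    # indoles
    e("B01", "NCCc1c[nH]c2ccccc12", "indole"),
    e("B02", "CNCCc1c[nH]c2ccccc12", "indole"),
    e("B03", "OC(=O)Cc1c[nH]c2ccccc12", "indole"),
    e("B04", "COc1ccc2[nH]ccc2c1", "indole"),
    e("B05", "Cc1c[nH]c2ccccc12", "indole"),
    e("B06", "O=Cc1c[nH]c2ccccc12", "indole"),
    e("B07", "Brc1ccc2[nH]ccc2c1", "indole"),
    e("B08", "CC(=O)NCCc1c[nH]c2ccc(OC)cc12", "indole"),
    e("B09", "Cc1cc2ccccc2[nH]1", "indole"),                # isomer of B05
    # benzamides / benzoic acids
    e("A01", "OC(=O)c1ccccc1", "benzamide"),
    e("A02", "Nc1ccc(C(=O)O)cc1", "benzamide"),
    e("A03", "NC(=O)c1ccccc1", "benzamide"),
    e("A04", "CNC(=O)c1ccccc1", "benzamide"),
    e("A05", "CC(=O)Nc1ccccc1", "benzamide"),               # isomer of A04
    e("A06", "OC(=O)c1ccc(Cl)cc1", "benzamide"),
    e("A07", "OC(=O)c1ccccc1O", "benzamide"),
    e("A08", "CC(=O)Oc1ccccc1C(=O)O", "benzamide"),
    e("A09", "Nc1ccccc1C(=O)O", "benzamide"),               # isomer of A02
    e("A10", "NC(=O)c1ccc(O)cc1", "benzamide"),
    e("A11", "NC(=O)c1ccc(C(N)=O)cc1", "benzamide"),
    # piperazines / pyridines
    e("C01", "c1ccc(N2CCNCC2)cc1", "piperazine"),
    e("C02", "c1ccnc(N2CCNCC2)c1", "piperazine"),
    e("C03", "CN1CCN(c2ccccc2)CC1", "piperazine"),
    e("C04", "c1ccc(-c2ccncc2)cc1", "piperazine"),
    e("C05", "c1ccc(-c2ccccn2)cc1", "piperazine"),          # isomer of C04
    e("C06", "OC(=O)c1cccnc1", "piperazine"),
    e("C07", "NC(=O)c1ccncc1", "piperazine"),
    # planted assay-interference structures
    e("P01", "O=C1C=CC(=O)C=C1", "liability"),              # para-quinone
    e("P02", "O=C1CSC(=S)N1Cc1ccccc1", "liability"),        # rhodanine
    e("P03", "Oc1ccc(N=Nc2ccccc2)cc1", "liability"),        # azo-phenol
    # redundant forms: salts, protonation states, re-ordered SMILES
    e("R01", "[Na+].[O-]C(=O)c1ccccc1", "benzamide", "A01"),
    e("R02", "NCCc1c[nH]c2ccccc12.Cl", "indole", "B01"),
    e("R03", "CN(C)CCC=C1c2ccccc2CCc2ccccc21.Cl", "tricyclic", "E01"),
    e("R04", "C[NH2+]CCc1c[nH]c2ccccc12", "indole", "B02"),
    e("R05", "[NH3+]c1ccc(C(=O)[O-])cc1", "benzamide", "A02"),
    e("R06", "Oc1ccccc1C", "phenol", "D01"),
    e("R07", "[Na+].[O-]C(=O)c1cccnc1", "piperazine", "C06"),
    e("R08", "Oc1ccccc1C(O)=O", "benzamide", "A07"),
    e("R09", "Cl.c1ccc(N2CCNCC2)cc1", "piperazine", "C01"),
    e("R10", "Oc1ccc(OC)cc1", "phenol", "D08"),
    e("R11", "Cl.CNCCC=C1c2ccccc2CCc2ccccc21", "tricyclic", "E02"),
    e("R12", "O=C1C=CC(=O)C=C1", "liability", "P01")
  ))
}

#' Nortriptyline reference structure
#'
#' SMILES of the screen's positive control, used by the optional
#' exclusion-by-similarity filter.
#' @return Character scalar SMILES.
#' @export
nortriptyline_smiles <- function() "CNCCC=C1c2ccccc2CCc2ccccc21"
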