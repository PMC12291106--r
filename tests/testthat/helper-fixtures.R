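# Shared fixtures and the independent substructure oracle.

# Independent brute-force substructure oracle: RDKit (python) enumerates
# unique matches for every (molecule, pattern) pair. Completely separate
# code path from the package's OpenBabel matcher.
rdkit_match_counts <- function(smiles, smarts) {
  req <- jsonlite::toJSON(list(smiles = smiles, smarts = smarts),
                          auto_unbox = FALSE)
  code <- paste(
    "import json,sys",
    "from rdkit import Chem, RDLogger",
    "RDLogger.DisableLog('rdApp.*')",
    "r=json.load(sys.stdin)",
    "mols=[Chem.MolFromSmiles(s) for s in r['smiles']]",
    "pats=[Chem.MolFromSmarts(p) for p in r['smarts']]",
    "out=[[len(m.GetSubstructMatches(p,uniquify=True)) for p in pats] for m in mols]",
    "json.dump(out,sys.stdout)",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(code)), input = as.character(req),
                 stdout = TRUE, stderr = FALSE)
  m <- jsonlite::fromJSON(paste(out, collapse = ""))
  matrix(as.integer(m), nrow = length(smiles), byrow = FALSE,
         dimnames = list(NULL, smarts))
}

# Whole-molecule TPSA from RDKit, the reference value for the pooled-limit
# check.
rdkit_tpsa <- function(smiles) {
  code <- paste(
    "import json,sys",
    "from rdkit import Chem, RDLogger",
    "from rdkit.Chem import Descriptors",
    "RDLogger.DisableLog('rdApp.*')",
    "s=json.load(sys.stdin)",
    "json.dump([Descriptors.TPSA(Chem.MolFromSmiles(x)) for x in s],sys.stdout)",
    sep = "\n")
  out <- system2("python", c("-c", shQuote(code)),
                 input = as.character(jsonlite::toJSON(smiles)),
                 stdout = TRUE, stderr = FALSE)
  as.numeric(jsonlite::fromJSON(paste(out, collapse = "")))
}

# A >= 20 molecule fixture on which the OpenBabel and RDKit SMARTS dialects
# agree (no hypervalent-nitro forms), drawn from the synthetic scaffold
# grid plus the example dataset.
oracle_fixture_smiles <- function() {
  spec <- synthetic_spec()
  grid <- expand.grid(sc = names(spec$scaffold_library),
                      fr = spec$substituent_library$fragment,
                      stringsAsFactors = FALSE)
  smi <- vapply(seq_len(nrow(grid)), function(i) {
    sprintf(spec$scaffold_library[[grid$sc[i]]], grid$fr[i])
  }, character(1))
  smi <- smi[!grepl("N(=O)=O", smi, fixed = TRUE)]
  ex <- example_modifier_dataset()
  unique(c(smi, ex$smiles[ex$id != "nba"]))
}

# Five single-SMARTS rules (dialect-neutral patterns) for the oracle
# equivalence check.
oracle_fixture_rules <- function() {
  pats <- c(amine = "[NX3;H2,H1]", aryl = "c1ccccc1", halo = "[F,Cl,Br,I]",
            thio = "[#16]", acid = "[CX3](=O)[OX2H1]")
  dirs <- c(1L, 1L, -1L, -1L, 1L)
  rule_set(lapply(seq_along(pats), function(i) {
    rule_spec(names(pats)[i], paste("contains", names(pats)[i]),
              list(clause(pred_smarts(pats[[i]]), dirs[i])))
  }))
}

write_tmp_csv <- function(df) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  path
}

tiny_dataset_df <- function() {
  data.frame(
    id = c("m1", "m2", "m3"),
    name = c("acetic", "benzoic", "glycine"),
    smiles = c("CC(=O)O", "OC(=O)c1ccccc1", "NCC(=O)O"),
    yield_percent = c(40, 55, 52),
    fe_loading = c(1.0, 1.2, 1.4),
    modifier_sbu = c(2.7, 1.6, 2.2),
    fe_hf = c(0.21, 0.24, 0.25),
    stringsAsFactors = FALSE
  )
}
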