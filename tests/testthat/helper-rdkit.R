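# RDKit (via the pre-installed python) as an independent third-party
# oracle for canonicalization equivalence and molecular formulas. Used
# on small fixed corpora only; the implementation never depends on it.

rdkit_oracle <- function(smiles) {
  script <- '
import sys
from rdkit import Chem
from rdkit.Chem.rdMolDescriptors import CalcMolFormula
for line in sys.stdin:
    smi = line.strip()
    if not smi:
        continue
    m = Chem.MolFromSmiles(smi)
    if m is None:
        print("ERROR\\tERROR")
    else:
        print(Chem.MolToSmiles(m) + "\\t" + CalcMolFormula(m))
'
  inp <- tempfile(); on.exit(unlink(inp))
  writeLines(smiles, inp)
  out <- suppressWarnings(
    system2("python", c("-c", shQuote(script)),
            stdin = inp, stdout = TRUE, stderr = FALSE))
  parts <- strsplit(out, "\t", fixed = TRUE)
  list(canonical = vapply(parts, `[`, character(1), 1),
       formula = vapply(parts, `[`, character(1), 2))
}

# our molecular formula (heavy atoms + implicit H), Hill order like RDKit
mol_formula <- function(mol) {
  counts <- table(mol$element)
  h <- sum(implicit_h(mol))
  syms <- names(counts)
  hill <- if ("C" %in% syms) {
    c("C", if (h > 0) "H", sort(setdiff(syms, "C")))
  } else {
    # RDKit puts H first for carbon-free formulas
    c(if (h > 0) "H", sort(syms))
  }
  paste0(vapply(hill, function(s) {
    k <- if (s == "H") h else as.integer(counts[[s]])
    paste0(s, if (k > 1L) k else "")
  }, character(1)), collapse = "")
}
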