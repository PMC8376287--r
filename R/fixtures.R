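#' Deterministic toy molecule library
#'
#' A curated, hard-coded set of small molecules covering every domain
#' preset: 1 / 2 / 3 aliphatic rings, 1-4 aromatic rings, 1 / 2-3
#' hydrogen-bond acceptors, 1 / 2-4 donors, plus charged species for the
#' dataset filter. Two calls return identical sets; every entry parses as
#' valid.
#'
#' @return A `molecule_set` (see [parse_molecules()]).
#' @export
make_toy_molecules <- function() {
  smiles <- c(
    # exactly one aliphatic ring
    "C1CCCCC1",             # cyclohexane
    "C1CCCC1",              # cyclopentane
    "CC1CCCCC1",            # methylcyclohexane
    "OC1CCCCC1",            # cyclohexanol
    "NC1CCCCC1",            # cyclohexylamine
    "C1CCCCCC1",            # cycloheptane
    "O=C1CCCC1",            # cyclopentanone
    "CC1CCC(C)CC1",         # 1,4-dimethylcyclohexane
    # two aliphatic rings
    "C1CCC2CCCCC2C1",       # decalin
    "C1CCC(CC1)C1CCCCC1",   # bicyclohexyl
    "C1CCC2(C1)CCCCC2",     # spiro[4.5]decane
    "C1CC2CCC1C2",          # norbornane
    "C1CCC(CC1)C1CCCC1",    # cyclohexylcyclopentane
    # three aliphatic rings
    "C1CCC2CC3CCCCC3CC2C1", # perhydroanthracene
    "C1CCC(CC1)C1CCCC1C1CCCC1",
    "C1CC2(CCC1)CCC1(CCCC1)CC2",
    # one aromatic ring
    "c1ccccc1",             # benzene
    "Cc1ccccc1",            # toluene
    "Oc1ccccc1",            # phenol
    "Nc1ccccc1",            # aniline
    "c1ccncc1",             # pyridine
    "COc1ccccc1",           # anisole
    "CCc1ccccc1",           # ethylbenzene
    # two aromatic rings
    "c1ccc2ccccc2c1",       # naphthalene
    "c1ccc(-c2ccccc2)cc1",  # biphenyl
    "c1ccc2[nH]ccc2c1",     # indole
    "c1ccc2ncccc2c1",       # quinoline
    "C(c1ccccc1)c1ccccc1",  # diphenylmethane
    # three aromatic rings
    "c1ccc2cc3ccccc3cc2c1", # anthracene
    "c1ccc(-c2ccc(-c3ccccc3)cc2)cc1",  # p-terphenyl
    "C(c1ccccc1)(c1ccccc1)c1ccccc1",   # triphenylmethane
    # four aromatic rings
    "c1cc2ccc3cccc4ccc(c1)c2c34",      # pyrene
    "C(c1ccccc1)(c1ccccc1)(c1ccccc1)c1ccccc1",  # tetraphenylmethane
    "c1ccc2cc3cc4ccccc4cc3cc2c1",      # naphthacene
    # one acceptor / one donor
    "CCO",                  # ethanol
    "CCCO",                 # 1-propanol
    "CCOCC",                # diethyl ether
    "CC(C)=O",              # acetone
    "CCN(CC)CC",            # triethylamine
    # 2-3 acceptors / 2-4 donors
    "OCCO",                 # ethylene glycol
    "OCC(O)CO",             # glycerol
    "COCCOC",               # 1,2-dimethoxyethane
    "C1COCCN1",             # morpholine
    "OCCNCCO",              # diethanolamine
    "NCCO",                 # ethanolamine
    "Oc1cccc(O)c1",         # resorcinol
    "OCC(O)C(O)CO",         # erythritol
    "OCC(CO)(CO)CO",        # pentaerythritol
    "NC(CO)(CO)CO",         # tromethamine
    # charged species (must fall to the dataset filter)
    "[NH4+]",
    "CC(=O)[O-]",
    "C[N+](C)(C)C"
  )
  parse_molecules(smiles)
}
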