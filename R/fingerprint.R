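## Circular (ECFP/Morgan) fingerprints of single molecules, computed via
## OpenBabel (ChemmineOB), and the planted fingerprint-to-radii dataset
## generator used to validate the regressor.

ob_ecfp_name <- function(radius) {
  nm <- c(`0` = "ECFP0", `1` = "ECFP2", `2` = "ECFP4", `3` = "ECFP6",
          `5` = "ECFP10")[as.character(radius)]
  if (is.na(nm))
    stop("unsupported ECFP neighbourhood radius ", radius,
         " (supported: 0, 1, 2, 3, 5)")
  nm
}

#' Circular (ECFP) fingerprint of a molecule
#'
#' Hashed circular fingerprint of the molecular graph: atom neighbourhoods
#' up to the given radius are encoded by iterated Morgan relabelling and
#' hashed into a fixed-length binary vector.  The 4096-bit OpenBabel ECFP
#' is folded down to `n_bits` by OR-ing bit blocks, the standard
#' fingerprint folding operation.  Deterministic for fixed inputs and
#' invariant under SMILES rewriting of the same molecule.
#'
#' @param smiles A single SMILES string.
#' @param radius Neighbourhood radius of the circular algorithm (default
#'   2, the ECFP4-equivalent).
#' @param n_bits Length of the folded binary vector (default 2048; at
#'   most 4096, and must divide 4096).
#' @return Integer 0/1 vector of length `n_bits` with attributes
#'   `smiles`, `radius`.
#' @examples
#' \donttest{
#' fp <- compute_fingerprint("c1ccccc1")
#' sum(fp)   # number of set bits for benzene
#' }
#' @export
compute_fingerprint <- function(smiles, radius = 2, n_bits = 2048) {
  stopifnot(is.character(smiles), length(smiles) == 1, nchar(smiles) > 0,
            n_bits >= 1, n_bits <= 4096, 4096 %% n_bits == 0)
  raw <- tryCatch(
    ChemmineOB::fingerprint_OB(
      ChemmineOB::forEachMol("SMILES", smiles, identity),
      ob_ecfp_name(radius)),
    error = function(e)
      stop("cannot parse SMILES \"", smiles, "\": ", conditionMessage(e),
           call. = FALSE))
  bits <- as.integer(as.logical(raw))
  folded <- as.integer(rowSums(matrix(bits, nrow = n_bits)) > 0)
  structure(folded, smiles = smiles, radius = radius)
}

#' Fingerprint matrix for a vector of molecules
#'
#' @param smiles Character vector of SMILES strings.
#' @inheritParams compute_fingerprint
#' @return Integer matrix, one row per molecule, `n_bits` columns.
#' @export
fingerprint_matrix <- function(smiles, radius = 2, n_bits = 2048) {
  t(vapply(smiles, compute_fingerprint, integer(n_bits),
           radius = radius, n_bits = n_bits, USE.NAMES = FALSE))
}

#' Built-in pool of small-molecule SMILES
#'
#' Valid SMILES of small aromatic and aliphatic molecules (polycyclic
#' aromatic hydrocarbons, heteroaromatics, simple aliphatics) used by the
#' synthetic dataset generator.  Linear alkanes can be appended to
#' enlarge the pool programmatically.
#'
#' @param n_alkanes Number of linear alkanes (ethane upward) to append.
#' @return Character vector of SMILES.
#' @export
smiles_pool <- function(n_alkanes = 0) {
  pool <- c(
    "c1ccccc1",                       # benzene
    "c1ccc2ccccc2c1",                 # naphthalene
    "c1ccc2cc3ccccc3cc2c1",           # anthracene
    "c1ccc2c(c1)ccc3ccccc23",         # phenanthrene
    "c1cc2ccc3cccc4ccc(c1)c2c34",     # pyrene
    "c1ccc2cc3cc4ccccc4cc3cc2c1",     # naphthacene
    "c1ccc2c(c1)cc1ccc3ccccc3c1c2",   # chrysene-like
    "c1ccc-2c(c1)-c1cccc3cccc-2c13",  # fluoranthene
    "C1=CC2=CC=C3C=CC4=CC5=CC=C6C=CC1=C1C2=C3C4=C5C61", # coronene-like
    "c1ccncc1",                       # pyridine
    "c1ccnnc1",                       # pyridazine
    "c1cnccn1",                       # pyrazine
    "c1ccc2ncccc2c1",                 # quinoline
    "c1ccc2cnccc2c1",                 # isoquinoline
    "c1ccc2[nH]ccc2c1",               # indole
    "c1ccc2occc2c1",                  # benzofuran
    "c1ccc2sccc2c1",                  # benzothiophene
    "c1ccoc1",                        # furan
    "c1ccsc1",                        # thiophene
    "c1cc[nH]c1",                     # pyrrole
    "c1cscn1",                        # thiazole
    "c1ccc(cc1)C#N",                  # benzonitrile
    "c1ccc(cc1)O",                    # phenol
    "c1ccc(cc1)N",                    # aniline
    "c1ccc(cc1)C",                    # toluene
    "c1ccc(cc1)F",                    # fluorobenzene
    "c1ccc(cc1)Cl",                   # chlorobenzene
    "c1ccc(cc1)Br",                   # bromobenzene
    "c1ccc(cc1)C(=O)C",               # acetophenone
    "c1ccc(cc1)C=O",                  # benzaldehyde
    "c1ccc(cc1)c1ccccc1",             # biphenyl
    "Cc1ccccc1C",                     # xylene
    "CC(C)c1ccccc1",                  # cumene
    "C1CCCCC1",                       # cyclohexane
    "C1CCCC1",                        # cyclopentane
    "CCO",                            # ethanol
    "CC(C)O",                         # isopropanol
    "CC(=O)C",                        # acetone
    "CCOC(=O)C",                      # ethyl acetate
    "CCN(CC)CC")                      # triethylamine
  if (n_alkanes > 0)
    pool <- c(pool, vapply(seq_len(n_alkanes) + 1,
                           function(k) paste(rep("C", k), collapse = ""), ""))
  pool
}

#' Generate a planted fingerprint-to-radii dataset
#'
#' Draws molecules (with replacement) from a SMILES pool, computes their
#' circular fingerprints, and produces target radii triples from a seeded
#' sparse linear map of fingerprint bits plus Gaussian noise; each triple
#' is then sorted descending (r1 >= r2 >= r3), matching the convention
#' for estimated ellipsoid radii.  The planted map is returned so
#' recovery can be scored.
#'
#' @param n Number of records.
#' @param molecules SMILES pool (default [smiles_pool()]).
#' @param radius,n_bits Fingerprint parameters.
#' @param n_active Number of active (weight-carrying) fingerprint bits,
#'   sampled among bits that vary across the pool.
#' @param coef_sd Standard deviation of the planted weights (nm).
#' @param base Baseline radii (nm) before the linear term.
#' @param sigma Gaussian noise standard deviation (nm).
#' @param seed Optional integer seed.
#' @return A list of class `"fingerprint_dataset"`: `X` (n x n_bits 0/1
#'   matrix), `Y` (n x 3 radii, nm), `smiles`, `radius`, `n_bits`,
#'   `planted` (active bit indices, weights, base, sigma).
#' @export
generate_ml_dataset <- function(n, molecules = smiles_pool(), radius = 2,
                                n_bits = 2048, n_active = 32,
                                coef_sd = 0.02, base = c(0.6, 0.45, 0.3),
                                sigma = 0.02, seed = NULL) {
  stopifnot(n >= 1, sigma >= 0, length(base) == 3)
  if (length(molecules) == 0) stop("empty molecule pool")
  if (!is.null(seed)) set.seed(seed)
  pool_fp <- fingerprint_matrix(molecules, radius, n_bits)
  varying <- which(apply(pool_fp, 2, function(col) length(unique(col)) > 1))
  if (length(varying) == 0)
    stop("no fingerprint bit varies across the molecule pool")
  n_active <- min(n_active, length(varying))
  active <- sort(sample(varying, n_active))
  coefs <- matrix(stats::rnorm(3 * n_active, 0, coef_sd), nrow = 3)
  pick <- sample(length(molecules), n, replace = TRUE)
  X <- pool_fp[pick, , drop = FALSE]
  Y <- X[, active, drop = FALSE] %*% t(coefs)
  Y <- sweep(Y, 2, base, "+")
  if (sigma > 0) Y <- Y + matrix(stats::rnorm(3 * n, 0, sigma), ncol = 3)
  Y <- pmax(Y, 0.02)                    # radii are physical lengths
  Y <- t(apply(Y, 1, sort, decreasing = TRUE))
  structure(list(X = X, Y = Y, smiles = molecules[pick], radius = radius,
                 n_bits = n_bits,
                 planted = list(active = active, coefs = coefs,
                                base = base, sigma = sigma)),
            class = "fingerprint_dataset")
}
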