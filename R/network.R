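#' @useDynLib xagen, .registration = TRUE
#' @importFrom stats setNames
NULL

# Species of the tissue factor pathway network. Complexes are written with
# underscores (TF_VIIa = the extrinsic tenase TF:VIIa); VIIIa1_L and VIIIa2
# are the A1-L and A2 fragments of dissociated factor VIIIa.
TF_PATHWAY_SPECIES <- c(
  "TF", "VII", "TF_VII", "VIIa", "TF_VIIa",
  "Xa", "IIa", "X", "TF_VIIa_X", "TF_VIIa_Xa",
  "IX", "TF_VIIa_IX", "IXa", "II", "VIII",
  "VIIIa", "IXa_VIIIa", "IXa_VIIIa_X", "VIIIa1_L", "VIIIa2",
  "V", "Va", "Xa_Va", "Xa_Va_II", "mIIa",
  "TFPI", "Xa_TFPI", "TF_VIIa_Xa_TFPI", "AT", "Xa_AT",
  "mIIa_AT", "IXa_AT", "IIa_AT", "TF_VIIa_AT"
)

# One row per reaction arrow: rate-constant key (must exist in the constants
# file), reactants and products as "+"-separated species. Catalytic species
# appear on both sides and cancel in the net stoichiometry but still enter
# the mass-action flux.
TF_PATHWAY_REACTIONS <- data.frame(
  rate = c(
    "tf_vii_on", "tf_vii_off", "tf_viia_on", "tf_viia_off",
    "viia_from_tf_viia", "viia_from_xa", "viia_from_iia",
    "tf_viia_x_on", "tf_viia_x_off", "tf_viia_x_cat",
    "tf_viia_xa_on", "tf_viia_xa_off",
    "tf_viia_ix_on", "tf_viia_ix_off", "tf_viia_ix_cat",
    "iia_from_xa", "viiia_from_iia",
    "ixa_viiia_on", "ixa_viiia_off",
    "ixa_viiia_x_on", "ixa_viiia_x_off", "ixa_viiia_x_cat",
    "viiia_diss", "viiia_assoc",
    "ixa_viiia_x_decay", "ixa_viiia_decay",
    "va_from_iia", "xa_va_on", "xa_va_off",
    "xa_va_ii_on", "xa_va_ii_off", "xa_va_ii_cat", "miia_to_iia",
    "xa_tfpi_on", "xa_tfpi_off",
    "tf_viia_xa_tfpi_on", "tf_viia_xa_tfpi_off", "tf_viia_plus_xa_tfpi",
    "xa_at", "miia_at", "ixa_at", "iia_at", "tf_viia_at"
  ),
  reactants = c(
    "TF+VII", "TF_VII", "TF+VIIa", "TF_VIIa",
    "TF_VIIa+VII", "Xa+VII", "IIa+VII",
    "TF_VIIa+X", "TF_VIIa_X", "TF_VIIa_X",
    "TF_VIIa+Xa", "TF_VIIa_Xa",
    "TF_VIIa+IX", "TF_VIIa_IX", "TF_VIIa_IX",
    "Xa+II", "IIa+VIII",
    "VIIIa+IXa", "IXa_VIIIa",
    "IXa_VIIIa+X", "IXa_VIIIa_X", "IXa_VIIIa_X",
    "VIIIa", "VIIIa1_L+VIIIa2",
    "IXa_VIIIa_X", "IXa_VIIIa",
    "IIa+V", "Xa+Va", "Xa_Va",
    "Xa_Va+II", "Xa_Va_II", "Xa_Va_II", "mIIa+Xa_Va",
    "Xa+TFPI", "Xa_TFPI",
    "TF_VIIa_Xa+TFPI", "TF_VIIa_Xa_TFPI", "TF_VIIa+Xa_TFPI",
    "Xa+AT", "mIIa+AT", "IXa+AT", "IIa+AT", "TF_VIIa+AT"
  ),
  products = c(
    "TF_VII", "TF+VII", "TF_VIIa", "TF+VIIa",
    "TF_VIIa+VIIa", "Xa+VIIa", "IIa+VIIa",
    "TF_VIIa_X", "TF_VIIa+X", "TF_VIIa_Xa",
    "TF_VIIa_Xa", "TF_VIIa+Xa",
    "TF_VIIa_IX", "TF_VIIa+IX", "TF_VIIa+IXa",
    "Xa+IIa", "IIa+VIIIa",
    "IXa_VIIIa", "VIIIa+IXa",
    "IXa_VIIIa_X", "IXa_VIIIa+X", "IXa_VIIIa+Xa",
    "VIIIa1_L+VIIIa2", "VIIIa",
    "VIIIa1_L+VIIIa2+X+IXa", "VIIIa1_L+VIIIa2+IXa",
    "IIa+Va", "Xa_Va", "Xa+Va",
    "Xa_Va_II", "Xa_Va+II", "Xa_Va+mIIa", "IIa+Xa_Va",
    "Xa_TFPI", "Xa+TFPI",
    "TF_VIIa_Xa_TFPI", "TF_VIIa_Xa+TFPI", "TF_VIIa_Xa_TFPI",
    "Xa_AT", "mIIa_AT", "IXa_AT", "IIa_AT", "TF_VIIa_AT"
  ),
  stringsAsFactors = FALSE
)

# Protein-moiety membership: every species containing one copy of a given
# precursor protein. VIIIa dissociation splits factor VIII into two fragments,
# so the VIII backbone is tracked as two separately conserved moieties.
TF_PATHWAY_MOIETIES <- list(
  TF   = c("TF", "TF_VII", "TF_VIIa", "TF_VIIa_X", "TF_VIIa_Xa",
           "TF_VIIa_IX", "TF_VIIa_Xa_TFPI", "TF_VIIa_AT"),
  VII  = c("VII", "TF_VII", "VIIa", "TF_VIIa", "TF_VIIa_X", "TF_VIIa_Xa",
           "TF_VIIa_IX", "TF_VIIa_Xa_TFPI", "TF_VIIa_AT"),
  X    = c("X", "TF_VIIa_X", "Xa", "TF_VIIa_Xa", "IXa_VIIIa_X", "Xa_Va",
           "Xa_Va_II", "Xa_TFPI", "TF_VIIa_Xa_TFPI", "Xa_AT"),
  IX   = c("IX", "TF_VIIa_IX", "IXa", "IXa_VIIIa", "IXa_VIIIa_X", "IXa_AT"),
  II   = c("II", "Xa_Va_II", "mIIa", "IIa", "mIIa_AT", "IIa_AT"),
  VIII_A1 = c("VIII", "VIIIa", "IXa_VIIIa", "IXa_VIIIa_X", "VIIIa1_L"),
  VIII_A2 = c("VIII", "VIIIa", "IXa_VIIIa", "IXa_VIIIa_X", "VIIIa2"),
  V    = c("V", "Va", "Xa_Va", "Xa_Va_II"),
  TFPI = c("TFPI", "Xa_TFPI", "TF_VIIa_Xa_TFPI"),
  AT   = c("AT", "Xa_AT", "mIIa_AT", "IXa_AT", "IIa_AT", "TF_VIIa_AT")
)

split_side <- function(x) strsplit(x, "+", fixed = TRUE)

#' Load and validate the mass-action rate constants
#'
#' Reads the rate-constant file shipped with the package (or a user override)
#' and checks that it provides one strictly positive value per reaction arrow
#' of the tissue factor pathway network.
#'
#' @param path Path to a YAML file of `key: value` pairs. Defaults to the
#'   bundled transcription of the Hockin et al. (2002) constants.
#' @return Named numeric vector of rate constants (association constants in
#'   1/(M s), first-order constants in 1/s).
#' @export
load_rate_constants <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rate_constants.yaml", package = "xagen")
  }
  if (!file.exists(path)) stop("rate constants file not found: ", path)
  raw <- yaml::read_yaml(path)
  k <- vapply(raw, as.numeric, numeric(1))
  needed <- unique(TF_PATHWAY_REACTIONS$rate)
  missing <- setdiff(needed, names(k))
  if (length(missing) > 0) {
    stop("rate constants file is incomplete; missing: ",
         paste(missing, collapse = ", "))
  }
  if (any(!is.finite(k)) || any(k <= 0)) {
    stop("all rate constants must be finite and strictly positive")
  }
  k
}

#' Construct the tissue factor pathway reaction network
#'
#' Builds the 34-species mass-action network of the extrinsic coagulation
#' model: tissue factor triggering via the extrinsic tenase (TF:VIIa),
#' feedback activation of fVII, fIX and fX activation, the intrinsic tenase
#' (fIXa:fVIIIa) and prothrombinase (fXa:fVa) complexes, meizothrombin and
#' thrombin formation, and stoichiometric inhibition by TFPI and antithrombin.
#'
#' @param rate_constants Named numeric vector as returned by
#'   [load_rate_constants()].
#' @param include_tf_viia_at Logical; keep the antithrombin inhibition of the
#'   TF:VIIa complex (present in the source model). Set `FALSE` to restrict
#'   antithrombin to thrombin, fIXa and fXa.
#' @return An object of class `tf_network`: species names, the reaction table
#'   with resolved rate constants, the net stoichiometry matrix `S`
#'   (species x reactions) and the protein-moiety matrix `M`
#'   (species x moieties).
#' @export
tf_pathway_network <- function(rate_constants = load_rate_constants(),
                               include_tf_viia_at = TRUE) {
  rx <- TF_PATHWAY_REACTIONS
  if (!include_tf_viia_at) rx <- rx[rx$rate != "tf_viia_at", ]
  rx$k <- unname(rate_constants[rx$rate])
  if (any(is.na(rx$k))) stop("unresolved rate constant")

  species <- TF_PATHWAY_SPECIES
  n_sp <- length(species)
  n_rx <- nrow(rx)
  S <- matrix(0L, n_sp, n_rx, dimnames = list(species, rx$rate))
  re <- split_side(rx$reactants)
  pr <- split_side(rx$products)
  for (j in seq_len(n_rx)) {
    for (sp in re[[j]]) S[sp, j] <- S[sp, j] - 1L
    for (sp in pr[[j]]) S[sp, j] <- S[sp, j] + 1L
  }

  M <- matrix(0L, n_sp, length(TF_PATHWAY_MOIETIES),
              dimnames = list(species, names(TF_PATHWAY_MOIETIES)))
  for (m in names(TF_PATHWAY_MOIETIES)) {
    M[TF_PATHWAY_MOIETIES[[m]], m] <- 1L
  }

  net <- structure(
    list(species = species, reactions = rx,
         reactant_sets = re, product_sets = pr, S = S, M = M),
    class = "tf_network"
  )
  # every reaction must conserve every protein moiety
  resid <- crossprod(M, S)
  if (any(resid != 0L)) {
    bad <- which(colSums(resid != 0L) > 0)
    stop("reactions violate moiety conservation: ",
         paste(colnames(S)[bad], collapse = ", "))
  }
  net
}

#' @export
print.tf_network <- function(x, ...) {
  cat("Tissue factor pathway network:",
      length(x$species), "species,",
      nrow(x$reactions), "reaction arrows\n")
  invisible(x)
}

#' Mass-action derivative of the network state
#'
#' Pure-R evaluation of the ODE right-hand side: for each reaction arrow the
#' flux is the rate constant times the product of reactant concentrations,
#' and each species' rate is the stoichiometry-weighted sum of fluxes.
#'
#' @param state Named numeric vector of species concentrations (mol/L), one
#'   entry per network species.
#' @param network A `tf_network`.
#' @return Named numeric vector of d(concentration)/dt in mol/L/s.
#' @export
network_derivative <- function(state, network) {
  stopifnot(inherits(network, "tf_network"))
  if (is.null(names(state))) names(state) <- network$species
  if (!identical(sort(names(state)), sort(network$species))) {
    stop("state must carry one entry per network species")
  }
  y <- state[network$species]
  flux <- vapply(seq_along(network$reactant_sets), function(j) {
    network$reactions$k[j] * prod(y[network$reactant_sets[[j]]])
  }, numeric(1))
  drop(network$S %*% flux)
}

# Flatten the network into the fixed-length parameter vector understood by
# the compiled mass-action engine (see src/massaction.c for the layout).
encode_network <- function(network) {
  n_rx <- nrow(network$reactions)
  slots <- 9L
  max_rx <- 64L
  if (n_rx > max_rx) stop("too many reactions for the compiled engine")
  p <- numeric(2 + max_rx * slots)
  p[1] <- length(network$species)
  p[2] <- n_rx
  idx <- setNames(seq_along(network$species) - 1L, network$species)
  for (j in seq_len(n_rx)) {
    re <- idx[network$reactant_sets[[j]]]
    pr <- idx[network$product_sets[[j]]]
    if (length(re) > 2 || length(pr) > 4) stop("reaction arity unsupported")
    block <- c(network$reactions$k[j],
               length(re), re, rep(-1, 2 - length(re)),
               length(pr), pr, rep(-1, 4 - length(pr)))
    p[2 + (j - 1) * slots + seq_len(slots)] <- block
  }
  p
}
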