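#' @import methods
NULL

#' Molecule: heavy-atom molecular graph
#'
#' Internal graph model of a single compound. Atoms are heavy atoms only
#' (hydrogens are implicit); each bond carries an order (1, 2, 3) and an
#' aromaticity flag. Aromaticity is perceived once, by OpenBabel, during
#' canonicalization, and every descriptor in the package consumes the same
#' perception.
#'
#' @slot id compound identifier (unique within a library)
#' @slot smiles canonical (aromatic) SMILES, as written by OpenBabel
#' @slot element per-atom element symbol ("C", "N", "Cl", ...)
#' @slot aromatic per-atom aromatic flag
#' @slot charge per-atom formal charge
#' @slot bondFrom,bondTo 1-based atom indices of each bond
#' @slot bondOrder integer bond order (aromatic bonds are stored as order 1
#'   with \code{bondAromatic} set)
#' @slot bondAromatic per-bond aromatic flag
#' @slot ringBond per-bond flag: TRUE iff the bond lies on a cycle
#' @exportClass Molecule
setClass("Molecule",
  slots = c(
    id = "character",
    smiles = "character",
    element = "character",
    aromatic = "logical",
    charge = "integer",
    bondFrom = "integer",
    bondTo = "integer",
    bondOrder = "integer",
    bondAromatic = "logical",
    ringBond = "logical"
  )
)

setValidity("Molecule", function(object) {
  n <- length(object@element)
  b <- length(object@bondFrom)
  msg <- character(0)
  if (n < 1L)
    msg <- c(msg, "molecule must have at least one heavy atom")
  if (length(object@aromatic) != n || length(object@charge) != n)
    msg <- c(msg, "per-atom slots must have one entry per atom")
  if (length(object@bondTo) != b || length(object@bondOrder) != b ||
      length(object@bondAromatic) != b || length(object@ringBond) != b)
    msg <- c(msg, "per-bond slots must have one entry per bond")
  if (b > 0 && (any(object@bondFrom < 1L) || any(object@bondTo > n) ||
                any(object@bondFrom == object@bondTo)))
    msg <- c(msg, "bond endpoints out of range")
  if (sum(object@ringBond) > b)
    msg <- c(msg, "ring bond count exceeds bond count")
  if (length(msg)) msg else TRUE
})

#' CompoundLibrary: an ordered collection of molecules
#'
#' Holds parsed molecules in input order, an id index, duplicate-structure
#' flags, and a per-library descriptor cache so fingerprints and path sets
#' are computed at most once.
#'
#' @slot molecules list of \linkS4class{Molecule}
#' @slot ids compound identifiers, parallel to \code{molecules}
#' @slot duplicated TRUE for entries whose canonical SMILES already occurred
#'   earlier in the library
#' @slot cache environment used for descriptor caching
#' @exportClass CompoundLibrary
setClass("CompoundLibrary",
  slots = c(
    molecules = "list",
    ids = "character",
    duplicated = "logical",
    cache = "environment"
  )
)

setValidity("CompoundLibrary", function(object) {
  n <- length(object@molecules)
  if (length(object@ids) != n)
    return("ids must parallel molecules")
  if (anyDuplicated(object@ids))
    return("compound ids must be unique")
  if (length(object@duplicated) != n)
    return("duplicated flags must parallel molecules")
  TRUE
})

#' FingerprintSet: binary descriptors for a set of compounds
#'
#' A logical matrix with one row per compound and one column per bit,
#' tagged with the descriptor kind. \code{kind} is one of \code{"path"}
#' (hashed linear-path fingerprint), \code{"keys"} (166-bit structural key
#' set) or \code{"combined"} (path bits followed by key bits).
#'
#' @slot bits logical matrix, rows = compounds, columns = bits
#' @slot ids compound identifiers (rownames of \code{bits})
#' @slot kind "path", "keys" or "combined"
#' @slot foldLevel number of OR-foldings applied to the path part
#' @slot version version tag of the key definition (keys/combined only)
#' @exportClass FingerprintSet
setClass("FingerprintSet",
  slots = c(
    bits = "matrix",
    ids = "character",
    kind = "character",
    foldLevel = "integer",
    version = "character"
  )
)

setValidity("FingerprintSet", function(object) {
  if (!is.logical(object@bits))
    return("bits must be a logical matrix")
  if (nrow(object@bits) != length(object@ids))
    return("one row per compound id required")
  if (!object@kind %in% c("path", "keys", "combined"))
    return("kind must be path, keys or combined")
  if (object@kind == "path" &&
      2048L %% (2L ^ object@foldLevel) != 0L)
    return("fold level incompatible with a power-of-two path length")
  TRUE
})

#' MetricSpec: one of the nine similarity schemes D1-D9
#'
#' D1 is Tanimoto on the 2,048-bit path fingerprint; D2 on the 166-bit
#' structural keys; D3/D4/D5 take the Max/Min/Avg consensus of the two pure
#' Tanimoto values; D6-D9 concatenate the (possibly folded) path fingerprint
#' with the keys and compute a single Tanimoto on 2,214 / 1,190 / 678 / 422
#' bits.
#'
#' @slot scheme "D1" .. "D9"
#' @slot mode "pure_path", "pure_keys", "max", "min", "avg" or "concat"
#' @slot pathBits length of the path part (2048, 1024, 512 or 256)
#' @slot usesKeys TRUE iff the scheme involves the structural keys
#' @exportClass MetricSpec
setClass("MetricSpec",
  slots = c(
    scheme = "character",
    mode = "character",
    pathBits = "integer",
    usesKeys = "logical"
  )
)

#' NeighborTable: thresholded similarity neighbors
#'
#' For each compound, the other compounds whose similarity exceeds the
#' threshold (strictly, by default), with the similarity values. Symmetric
#' by construction; no self-neighbors.
#'
#' @slot ids compound identifiers
#' @slot nbr list of integer vectors of neighbor positions, each sorted by
#'   descending similarity then ascending position
#' @slot sim list of numeric vectors parallel to \code{nbr}
#' @slot threshold similarity threshold in (0, 1]
#' @slot scheme label of the similarity scheme used
#' @slot strict TRUE for "> threshold", FALSE for ">="
#' @exportClass NeighborTable
setClass("NeighborTable",
  slots = c(
    ids = "character",
    nbr = "list",
    sim = "list",
    threshold = "numeric",
    scheme = "character",
    strict = "logical"
  )
)

setValidity("NeighborTable", function(object) {
  n <- length(object@ids)
  if (length(object@nbr) != n || length(object@sim) != n)
    return("neighbor and similarity lists must parallel ids")
  if (object@threshold <= 0 || object@threshold > 1)
    return("threshold must lie in (0, 1]")
  TRUE
})

#' ClusterResult: a partition of a library
#'
#' Every compound belongs to exactly one cluster; singletons are clusters of
#' size one. Cluster ids are dense integers assigned in descending
#' cluster-size order, ties broken by the smallest member position.
#'
#' @slot ids compound identifiers
#' @slot labels integer cluster id per compound
#' @slot method similarity-scheme label or "SCA"
#' @slot parameters list of the parameters the clustering was run with
#' @exportClass ClusterResult
setClass("ClusterResult",
  slots = c(
    ids = "character",
    labels = "integer",
    method = "character",
    parameters = "list"
  )
)

setValidity("ClusterResult", function(object) {
  if (length(object@labels) != length(object@ids))
    return("labels must parallel ids")
  if (length(object@labels) && any(is.na(object@labels)))
    return("every compound must carry a cluster label")
  TRUE
})

#' SelectionResult: picks of the Seed/Refill protocol
#'
#' Ordered picks with provenance: the phase each pick was made in, the
#' cluster it came from, and its rank. Refill results contain the seed picks
#' they extend, so a complete Phase I + Phase II selection is one object.
#'
#' @slot ids picked compound identifiers, in pick order
#' @slot phase "seed" or "refill", per pick
#' @slot cluster source cluster id per pick (NA for random selection)
#' @slot rank 1-based pick rank
#' @slot targetN total number of picks requested
#' @slot scheme similarity-scheme label, or "random"
#' @slot rngSeed RNG seed for random selection (NA otherwise)
#' @slot shortfall TRUE if the pool was exhausted before targetN
#' @slot parameters list of selection parameters
#' @exportClass SelectionResult
setClass("SelectionResult",
  slots = c(
    ids = "character",
    phase = "character",
    cluster = "integer",
    rank = "integer",
    targetN = "integer",
    scheme = "character",
    rngSeed = "integer",
    shortfall = "logical",
    parameters = "list"
  )
)

setValidity("SelectionResult", function(object) {
  n <- length(object@ids)
  if (anyDuplicated(object@ids))
    return("a compound may be picked at most once")
  if (length(object@phase) != n || length(object@cluster) != n ||
      length(object@rank) != n)
    return("per-pick slots must parallel ids")
  TRUE
})
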