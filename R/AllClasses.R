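#' @import methods
#' @importFrom stats sd runif setNames
#' @importFrom utils read.delim write.table head
#' @useDynLib CrystalContacts, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.AA_321 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
             GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
             LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
             SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
             MSE = "M", SEC = "U")

#' Crystallographic symmetry operator
#'
#' An affine operator in the fractional basis: \code{x' = rot \%*\% x + trans
#' + cellShift}. \code{rot} is an integer-valued 3x3 matrix with determinant
#' +1 or -1 and entries in \{-1, 0, 1\} (all crystallographic settings used
#' here), \code{trans} the intra-cell translation and \code{cellShift} added
#' whole unit-cell translations, kept separate for bookkeeping when the
#' operator relates two specific chain images.
#'
#' @slot rot 3x3 numeric matrix, integer-valued.
#' @slot trans numeric(3), fractional translation.
#' @slot cellShift numeric(3), integer-valued unit-cell translation.
#' @export
setClass("SymOperator", representation(
    rot = "matrix", trans = "numeric", cellShift = "numeric"))

setValidity("SymOperator", function(object) {
    msg <- NULL
    if (!all(dim(object@rot) == c(3L, 3L)))
        msg <- c(msg, "rot must be 3x3")
    else {
        if (!all(object@rot %in% c(-1, 0, 1)))
            msg <- c(msg, "rot entries must be in {-1, 0, 1}")
        if (abs(abs(det(object@rot)) - 1) > 1e-9)
            msg <- c(msg, "det(rot) must be +1 or -1")
    }
    if (length(object@trans) != 3L || any(!is.finite(object@trans)))
        msg <- c(msg, "trans must be finite numeric(3)")
    if (length(object@cellShift) != 3L ||
        any(abs(object@cellShift - round(object@cellShift)) > 1e-9))
        msg <- c(msg, "cellShift must be integer-valued numeric(3)")
    if (is.null(msg)) TRUE else msg
})

#' Geometric classification of a symmetry operator
#'
#' The operator-type vocabulary used for per-interface operator labels:
#' \code{AU} (non-crystallographic pair within the asymmetric unit),
#' \code{XT} (whole cell translation), \code{FT} (fractional translation,
#' from lattice centering), pure rotations \code{2}, \code{3}, \code{4},
#' \code{6}, screw axes \code{2S}, \code{3S}, \code{4S}, \code{6S}, and the
#' improper types \code{-1}, \code{-4}, \code{GL}. \code{isInfinite} is
#' \code{TRUE} exactly for the translation and screw types
#' \{XT, FT, 2S, 3S, 4S, 6S\}, the operators that generate open (infinite)
#' assemblies and therefore can only be crystal contacts.
#'
#' @slot code character(1), one of the codes above.
#' @slot fold integer(1), rotational fold (1 for AU/XT/FT).
#' @slot isProper logical(1), determinant +1.
#' @slot screw numeric(3), intrinsic (screw/glide) translation, fractional.
#' @slot isInfinite logical(1), operator generates an infinite assembly.
#' @export
setClass("OperatorClass", representation(
    code = "character", fold = "integer", isProper = "logical",
    screw = "numeric", isInfinite = "logical"))

setValidity("OperatorClass", function(object) {
    codes <- c("AU", "XT", "FT", "2", "3", "4", "6",
               "2S", "3S", "4S", "6S", "-1", "-4", "GL")
    msg <- NULL
    if (!(object@code %in% codes))
        msg <- c(msg, paste("unknown code", object@code))
    if (object@code %in% c("AU", "XT", "FT") && object@fold != 1L)
        msg <- c(msg, "translation-type codes must have fold 1")
    if (object@code %in% c("2S", "3S", "4S", "6S") &&
        all(abs(object@screw) < 1e-9))
        msg <- c(msg, "screw codes require a non-zero screw component")
    inf <- object@code %in% c("XT", "FT", "2S", "3S", "4S", "6S")
    if (!identical(object@isInfinite, inf))
        msg <- c(msg, "isInfinite must hold exactly for {XT,FT,2S,3S,4S,6S}")
    if (is.null(msg)) TRUE else msg
})

#' A chain model: observed residues and atoms of one polymer chain
#'
#' The sequence is taken from the observed residues (not the deposited
#' full-entity sequence), since accessible areas and interface regions are
#' defined on observed atoms. Atom coordinates are orthogonal Angstrom.
#'
#' @slot chainId character(1).
#' @slot sequence character(1), one-letter amino-acid string.
#' @slot resNames character, 3-letter residue names.
#' @slot resNos integer, author residue numbers.
#' @slot atoms data.frame with columns \code{serial}, \code{element},
#'   \code{name}, \code{resIndex} (1-based index into the residue list),
#'   \code{x}, \code{y}, \code{z}, \code{radius} (van der Waals, Angstrom).
#' @slot isProtein logical(1); only protein chains enter interface
#'   analysis.
#' @export
setClass("ChainModel", representation(
    chainId = "character", sequence = "character",
    resNames = "character", resNos = "integer",
    atoms = "data.frame", isProtein = "logical"))

setValidity("ChainModel", function(object) {
    msg <- NULL
    if (nchar(object@sequence) != length(object@resNames))
        msg <- c(msg, "sequence length must equal residue count")
    need <- c("serial", "element", "name", "resIndex", "x", "y", "z",
              "radius")
    if (!all(need %in% names(object@atoms)))
        msg <- c(msg, "atoms must have serial/element/name/resIndex/x/y/z/radius")
    else {
        if (nrow(object@atoms) &&
            (any(object@atoms$radius <= 0) ||
             any(!is.finite(as.matrix(object@atoms[, c("x", "y", "z")])))))
            msg <- c(msg, "atom radii must be positive and coords finite")
        if (nrow(object@atoms) &&
            (min(object@atoms$resIndex) < 1L ||
             max(object@atoms$resIndex) > length(object@resNames)))
            msg <- c(msg, "atom resIndex out of residue range")
    }
    if (is.null(msg)) TRUE else msg
})

#' Crystal unit cell
#'
#' Cell lengths (Angstrom), angles (degrees) and the derived
#' orthogonalization matrix (standard PDB convention: a along x, b in the
#' xy plane) mapping fractional to orthogonal Angstrom coordinates.
#'
#' @slot a,b,c numeric(1), cell edges in Angstrom.
#' @slot alpha,beta,gamma numeric(1), cell angles in degrees.
#' @slot orthMat 3x3 numeric matrix, fractional-to-orthogonal.
#' @export
setClass("CrystalCell", representation(
    a = "numeric", b = "numeric", c = "numeric",
    alpha = "numeric", beta = "numeric", gamma = "numeric",
    orthMat = "matrix"))

setValidity("CrystalCell", function(object) {
    msg <- NULL
    if (any(c(object@a, object@b, object@c) <= 0))
        msg <- c(msg, "cell lengths must be positive")
    ang <- c(object@alpha, object@beta, object@gamma)
    if (any(ang <= 0) || any(ang >= 180))
        msg <- c(msg, "cell angles must lie in (0, 180)")
    if (abs(det(object@orthMat)) < 1e-9)
        msg <- c(msg, "orthogonalization matrix must be invertible")
    if (is.null(msg)) TRUE else msg
})

#' A crystal structure with cell, symmetry and chain models
#'
#' Root input object for interface analysis. Chains are stored as a list of
#' chain models (see \code{\link{chainModel}}); only protein chains enter
#' interface analysis. Resolution and free R-factor are \code{NA} when not
#' reported (for example for NMR entries, which carry only the identity
#' operator and a placeholder cell).
#'
#' @slot entryId character(1).
#' @slot chains list of chain models.
#' @slot cell CrystalCell.
#' @slot spacegroup character(1), Hermann-Mauguin symbol.
#' @slot operators list of \linkS4class{SymOperator}; includes the identity.
#' @slot resolution numeric(1), Angstrom or NA.
#' @slot rFree numeric(1), fraction or NA.
#' @slot experimentalMethod character(1): "XRAY", "NMR" or "OTHER".
#' @slot authorBiounit list of (chainId, operator fingerprint) pairs making
#'   up the depositor-annotated assembly, or empty.
#' @export
setClass("CrystalStructure", representation(
    entryId = "character", chains = "list", cell = "CrystalCell",
    spacegroup = "character", operators = "list",
    resolution = "numeric", rFree = "numeric",
    experimentalMethod = "character", authorBiounit = "list"))

setValidity("CrystalStructure", function(object) {
    msg <- NULL
    if (length(object@operators) < 1L)
        msg <- c(msg, "operators must be non-empty")
    else {
        hasId <- any(vapply(object@operators, function(op)
            all(op@rot == diag(3)) && all(abs(op@trans) < 1e-9) &&
            all(op@cellShift == 0), logical(1)))
        if (!hasId) msg <- c(msg, "operators must include the identity")
    }
    if (!(object@experimentalMethod %in% c("XRAY", "NMR", "OTHER")))
        msg <- c(msg, "experimentalMethod must be XRAY, NMR or OTHER")
    if (object@experimentalMethod == "NMR" && length(object@operators) > 1L)
        msg <- c(msg, "NMR entries carry only the identity operator")
    if (is.null(msg)) TRUE else msg
})

#' A pairwise lattice interface
#'
#' One deduplicated contact between a reference chain and a (possibly
#' symmetry-transformed) partner chain image, with its buried surface area,
#' contact residue pairs and per-residue accessible/buried areas from which
#' core/rim/surface regions are derived at any burial threshold.
#'
#' @slot id integer(1), 1-based rank by descending area.
#' @slot chainA,chainB character(1), chain identifiers.
#' @slot operator \linkS4class{SymOperator} mapping chain B's reference copy
#'   onto its contacting image (identity + zero shift for AU pairs).
#' @slot opClass \linkS4class{OperatorClass} of that operator.
#' @slot area numeric(1), buried surface area in Angstrom^2
#'   ((ASA_A + ASA_B - ASA_AB)/2).
#' @slot contacts data.frame with columns \code{resA}, \code{resB} (1-based
#'   residue indices) of residue pairs within the contact distance.
#' @slot asaA,asaB numeric, per-residue accessible area of the isolated
#'   partner.
#' @slot bsaA,bsaB numeric, per-residue area buried on complexation.
#' @export
setClass("Interface", representation(
    id = "integer", chainA = "character", chainB = "character",
    operator = "SymOperator", opClass = "OperatorClass",
    area = "numeric", contacts = "data.frame",
    asaA = "numeric", asaB = "numeric",
    bsaA = "numeric", bsaB = "numeric"))

setValidity("Interface", function(object) {
    msg <- NULL
    if (object@area < 0) msg <- c(msg, "area must be >= 0")
    if (any(object@bsaA < -1e-6) || any(object@bsaB < -1e-6))
        msg <- c(msg, "per-residue buried area must be >= 0")
    if (length(object@asaA) != length(object@bsaA) ||
        length(object@asaB) != length(object@bsaB))
        msg <- c(msg, "asa/bsa vectors must be parallel")
    if (is.null(msg)) TRUE else msg
})

#' Per-residue sequence entropy mapped onto a chain
#'
#' Shannon entropies (bits) of alignment columns, placed on the observed
#' residues of a chain; \code{NA} where a residue maps to no column. A
#' profile computed from fewer than the required number of homologs is
#' flagged insufficient and the evolutionary indicators abstain.
#'
#' @slot entropy numeric, bits, one per chain residue (NA allowed).
#' @slot nHomologsUsed integer(1), homolog rows used (query excluded).
#' @slot identityCutoff numeric(1), homolog identity cutoff applied.
#' @slot insufficient logical(1).
#' @export
setClass("EntropyProfile", representation(
    entropy = "numeric", nHomologsUsed = "integer",
    identityCutoff = "numeric", insufficient = "logical"))

setValidity("EntropyProfile", function(object) {
    msg <- NULL
    ent <- object@entropy[!is.na(object@entropy)]
    if (length(ent) && (any(ent < -1e-9) || any(ent > log2(26) + 1e-9)))
        msg <- c(msg, "entropies must lie in [0, log2(alphabet)]")
    if (object@nHomologsUsed < 0L)
        msg <- c(msg, "nHomologsUsed must be >= 0")
    if (is.null(msg)) TRUE else msg
})

#' Classification result for one interface
#'
#' The three indicators (core-residue count at the geometric burial
#' threshold, core/rim mean-entropy ratio, core-versus-surface sampling
#' z-score), their individual calls, the consensus call and the
#' robust-call flag.
#'
#' @slot interfaceId integer(1).
#' @slot nCoreGeom integer(1), core residues over both partners.
#' @slot coreRimRatio numeric(1) or NA.
#' @slot coreSurfaceScore numeric(1) or NA.
#' @slot callGeometry,callCoreRim,callCoreSurface character(1):
#'   "BIO", "XTAL" or "NOPRED".
#' @slot consensus character(1): "BIO", "XTAL" or "NOPRED".
#' @slot robust logical(1).
#' @export
setClass("InterfaceCall", representation(
    interfaceId = "integer", nCoreGeom = "integer",
    coreRimRatio = "numeric", coreSurfaceScore = "numeric",
    callGeometry = "character", callCoreRim = "character",
    callCoreSurface = "character", consensus = "character",
    robust = "logical"))

setValidity("InterfaceCall", function(object) {
    lev <- c("BIO", "XTAL", "NOPRED")
    msg <- NULL
    for (f in c("callGeometry", "callCoreRim", "callCoreSurface",
                "consensus"))
        if (!(slot(object, f) %in% lev))
            msg <- c(msg, paste(f, "must be BIO, XTAL or NOPRED"))
    if (isTRUE(object@robust) && object@consensus == "NOPRED")
        msg <- c(msg, "a robust call cannot be NOPRED")
    if (is.null(msg)) TRUE else msg
})

#' Homolog alignment for one query chain
#'
#' An aligned-FASTA multiple sequence alignment: the query row first, then
#' homolog rows, all of equal width, with the per-row sequence identity to
#' the query (computed over non-gap query columns; a homolog gap counts as
#' a mismatch).
#'
#' @slot queryId character(1).
#' @slot ids character, row identifiers (query first).
#' @slot seqs character, aligned sequences with "-" gaps (query first).
#' @slot identityToQuery numeric, per row; 1 for the query itself.
#' @export
setClass("HomologAlignment", representation(
    queryId = "character", ids = "character", seqs = "character",
    identityToQuery = "numeric"))

setValidity("HomologAlignment", function(object) {
    msg <- NULL
    if (length(object@seqs) < 1L)
        msg <- c(msg, "alignment must contain at least the query row")
    if (length(unique(nchar(object@seqs))) > 1L)
        msg <- c(msg, "alignment rows must have equal length")
    if (length(object@ids) != length(object@seqs) ||
        length(object@identityToQuery) != length(object@seqs))
        msg <- c(msg, "ids/seqs/identityToQuery must be parallel")
    if (is.null(msg)) TRUE else msg
})
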