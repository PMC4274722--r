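#' Construct a symmetry operator
#'
#' @param rot 3x3 integer-valued matrix in the fractional basis.
#' @param trans Numeric(3) fractional translation.
#' @param cellShift Numeric(3) integer-valued added unit-cell translation.
#' @return A \linkS4class{SymOperator}.
#' @export
symOperator <- function(rot = diag(3), trans = c(0, 0, 0),
                        cellShift = c(0, 0, 0)) {
    new("SymOperator", rot = matrix(as.numeric(rot), 3, 3),
        trans = as.numeric(trans), cellShift = as.numeric(cellShift))
}

#' @rdname symOperator
#' @export
identityOperator <- function() symOperator()

#' Total translation of an operator (trans + cellShift)
#' @param op A \linkS4class{SymOperator}.
#' @return Numeric(3), fractional.
#' @export
totalTranslation <- function(op) op@trans + op@cellShift

#' Test for the identity operator
#' @param op A \linkS4class{SymOperator}.
#' @param includeShift If TRUE (default) a non-zero cell shift disqualifies.
#' @return Logical(1).
#' @export
isIdentityOperator <- function(op, includeShift = TRUE) {
    t <- if (includeShift) totalTranslation(op) else op@trans
    all(abs(op@rot - diag(3)) < 1e-9) && all(abs(t) < 1e-9)
}

#' Compose two symmetry operators
#'
#' Returns the operator applying \code{op2} first, then \code{op1}
#' (\code{x -> op1(op2(x))}). Cell shifts of the inputs are folded into the
#' translation of the result.
#'
#' @param op1,op2 \linkS4class{SymOperator} objects.
#' @return A \linkS4class{SymOperator} with zero cellShift slot.
#' @export
composeOperators <- function(op1, op2) {
    t1 <- totalTranslation(op1)
    t2 <- totalTranslation(op2)
    symOperator(op1@rot %*% op2@rot,
                as.numeric(op1@rot %*% t2) + t1)
}

#' Invert a symmetry operator
#' @param op A \linkS4class{SymOperator}.
#' @return The inverse operator (cell shift folded into the translation).
#' @export
invertOperator <- function(op) {
    rinv <- round(solve(op@rot))
    symOperator(rinv, -as.numeric(rinv %*% totalTranslation(op)))
}

#' Geometrically classify a symmetry operator
#'
#' Classifies the operator relating two chain images, including its cell
#' shift, into the operator-type vocabulary (see
#' \linkS4class{OperatorClass}). Pure rotations are distinguished from
#' screw axes by the intrinsic translation
#' \code{w = (1/n) sum_k rot^k trans}, the projection of the total
#' translation onto the rotation axis; the location part of the
#' translation (which only moves the axis) is discarded. Translation and
#' screw operators generate open, infinite assemblies and are flagged
#' \code{isInfinite}.
#'
#' @param op A \linkS4class{SymOperator} (as applied between two specific
#'   chain instances, cell shift included).
#' @param tol Tolerance for a "zero" screw component, fractional units.
#' @return An \linkS4class{OperatorClass}.
#' @examples
#' classifyOperator(symOperator(diag(c(-1, 1, -1)), c(0, 1/2, 0)))@code # "2S"
#' @export
classifyOperator <- function(op, tol = 1e-6) {
    R <- round(op@rot)
    Tt <- totalTranslation(op)
    d <- round(det(R))
    mkClass <- function(code, fold, proper, screw = c(0, 0, 0)) {
        new("OperatorClass", code = code, fold = as.integer(fold),
            isProper = proper, screw = as.numeric(screw),
            isInfinite = code %in% c("XT", "FT", "2S", "3S", "4S", "6S"))
    }
    if (all(R == diag(3))) {
        if (all(abs(Tt) < tol)) return(mkClass("AU", 1L, TRUE))
        if (all(abs(Tt - round(Tt)) < tol)) return(mkClass("XT", 1L, TRUE))
        return(mkClass("FT", 1L, TRUE, Tt))
    }
    if (d == 1) {
        tr <- round(sum(diag(R)))
        fold <- switch(as.character(tr),
                       "-1" = 2L, "0" = 3L, "1" = 4L, "2" = 6L,
                       stop("non-crystallographic rotation (trace ", tr, ")"))
        # intrinsic translation: average of T over the cyclic group of R
        w <- numeric(3)
        Rk <- diag(3)
        for (k in seq_len(fold)) {
            w <- w + as.numeric(Rk %*% Tt)
            Rk <- R %*% Rk
        }
        w <- w / fold
        # the intrinsic translation is NOT reduced modulo the lattice:
        # between two specific chain instances a rotation combined with a
        # whole-cell axial translation still walks, i.e. is screw-like
        if (all(abs(w) < tol))
            return(mkClass(as.character(fold), fold, TRUE))
        return(mkClass(paste0(fold, "S"), fold, TRUE, w))
    }
    # improper: rotoinversion -n where -R is a proper n-fold
    S <- -R
    if (all(S == diag(3))) return(mkClass("-1", 2L, FALSE))
    trS <- round(sum(diag(S)))
    foldS <- switch(as.character(trS),
                    "-1" = 2L, "0" = 3L, "1" = 4L, "2" = 6L,
                    stop("non-crystallographic improper operator"))
    if (foldS == 2L) {
        # R is a mirror; glide component is the in-plane intrinsic part
        w <- (Tt + as.numeric(R %*% Tt)) / 2
        return(mkClass("GL", 2L, FALSE, w))
    }
    if (foldS == 4L) return(mkClass("-4", 4L, FALSE))
    stop("rotoinversion -", foldS,
         " is outside the supported operator vocabulary")
}

# Canonical fingerprint text for one operator: triplet of rot and the
# fractional part of the total translation, "|" the integer part.
#' Canonical operator fingerprint
#'
#' A canonical text form of an operator, stable under equivalent
#' representations (cell shift folded in, translation split into its
#' fractional and whole-cell parts), used to match interfaces across call
#' sets and to deduplicate lattice contacts.
#'
#' @param op A \linkS4class{SymOperator}.
#' @return Character(1), e.g. \code{"x,y,z|0,0,0"} for the identity.
#' @export
operatorFingerprint <- function(op) {
    Tt <- totalTranslation(op)
    shift <- floor(Tt + 1e-9)
    frac <- Tt - shift
    canon <- symOperator(op@rot, frac)
    paste0(operatorTriplet(canon), "|",
           paste(round(shift), collapse = ","))
}

#' Unordered fingerprint pair of an interface operator
#'
#' An interface seen from partner A (operator g) and from partner B
#' (operator g^-1) is the same physical contact; the sorted pair of the
#' two fingerprints is therefore direction-independent.
#'
#' @param op A \linkS4class{SymOperator}.
#' @return Character(1): the two fingerprints, sorted and joined by "||".
#' @export
fingerprintPair <- function(op) {
    fps <- sort(c(operatorFingerprint(op),
                  operatorFingerprint(invertOperator(op))))
    paste(fps, collapse = "||")
}

#' @describeIn classifyOperator show method for OperatorClass
#' @param object An \linkS4class{OperatorClass}.
#' @export
setMethod("show", "OperatorClass", function(object) {
    cat("OperatorClass:", object@code,
        sprintf("(fold %d, %s%s)\n", object@fold,
                if (object@isProper) "proper" else "improper",
                if (object@isInfinite) ", infinite assembly" else ""))
})

setMethod("show", "SymOperator", function(object) {
    cat("SymOperator:", operatorFingerprint(object), "\n")
})
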