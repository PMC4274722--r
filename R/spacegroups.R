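# Embedded space-group operator table (sohncke groups used by the fixture
# generator plus a few extras for property tests). Triplets are the standard
# International Tables general positions.

.SPACEGROUP_TABLE <- list(
    "P 1" = c("x,y,z"),
    "P 1 21 1" = c("x,y,z", "-x,y+1/2,-z"),
    "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2",
                     "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2"),
    "P 43 21 2" = c("x,y,z", "-y+1/2,x+1/2,z+3/4", "-x,-y,z+1/2",
                    "y+1/2,-x+1/2,z+1/4", "x+1/2,-y+1/2,-z+1/4",
                    "-y,-x,-z+1/2", "-x+1/2,y+1/2,-z+3/4", "y,x,-z"),
    "C 1 2 1" = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
    "P 61" = c("x,y,z", "x-y,x,z+1/6", "-y,x-y,z+1/3", "-x,-y,z+1/2",
               "-x+y,-x,z+2/3", "y,-x+y,z+5/6"),
    "P 31" = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3"),
    "P 32 2 1" = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3",
                   "y,x,-z", "x-y,-y,-z+1/3", "-x,-x+y,-z+2/3"),
    "P 65 2 2" = c("x,y,z", "x-y,x,z+5/6", "-y,x-y,z+2/3", "-x,-y,z+1/2",
                   "-x+y,-x,z+1/3", "y,-x+y,z+1/6", "-y,-x,-z+1/6",
                   "-x,-x+y,-z+1/3", "-x+y,y,-z+1/2", "y,x,-z+2/3",
                   "x,x-y,-z+5/6", "x-y,-y,-z"),
    "I 2 2 2" = c("x,y,z", "-x,-y,z", "x,-y,-z", "-x,y,-z",
                  "x+1/2,y+1/2,z+1/2", "-x+1/2,-y+1/2,z+1/2",
                  "x+1/2,-y+1/2,-z+1/2", "-x+1/2,y+1/2,-z+1/2"))

.SPACEGROUP_ALIASES <- c(
    "P1" = "P 1",
    "P21" = "P 1 21 1", "P 21" = "P 1 21 1", "P1211" = "P 1 21 1",
    "P212121" = "P 21 21 21",
    "P43212" = "P 43 21 2",
    "C2" = "C 1 2 1", "C 2" = "C 1 2 1", "C121" = "C 1 2 1",
    "P61" = "P 61", "P31" = "P 31",
    "P3221" = "P 32 2 1", "P6522" = "P 65 2 2", "I222" = "I 2 2 2")

.canonicalSpacegroup <- function(symbol) {
    s <- trimws(symbol)
    if (s %in% names(.SPACEGROUP_TABLE)) return(s)
    key <- gsub(" ", "", s)
    if (key %in% names(.SPACEGROUP_ALIASES))
        return(unname(.SPACEGROUP_ALIASES[key]))
    NA_character_
}

#' Space groups with embedded operator tables
#'
#' @return Character vector of Hermann-Mauguin symbols resolvable by
#'   \code{\link{spaceGroupOperators}}.
#' @export
supportedSpaceGroups <- function() names(.SPACEGROUP_TABLE)

#' Symmetry operators of a space group
#'
#' Resolves a Hermann-Mauguin symbol (spacing-insensitive, with common
#' short aliases such as "P21" or "C2") against the embedded operator
#' table and returns the general-position operators.
#'
#' @param symbol Space-group symbol, e.g. \code{"P 1 21 1"}.
#' @return List of \linkS4class{SymOperator}; the first is the identity.
#' @examples
#' length(spaceGroupOperators("P 21 21 21"))  # 4
#' @export
spaceGroupOperators <- function(symbol) {
    canon <- .canonicalSpacegroup(symbol)
    if (is.na(canon))
        stop("unknown space-group symbol '", symbol,
             "'; supported: ", paste(supportedSpaceGroups(), collapse = ", "))
    lapply(.SPACEGROUP_TABLE[[canon]], parseOperatorTriplet)
}

.FRACTIONS <- c("1/2" = 1/2, "1/3" = 1/3, "2/3" = 2/3, "1/4" = 1/4,
                "3/4" = 3/4, "1/6" = 1/6, "5/6" = 5/6, "1/12" = 1/12)

#' Parse a crystallographic triplet such as "-x,y+1/2,-z"
#'
#' @param triplet Character(1) in "x,y,z" notation.
#' @return A \linkS4class{SymOperator} with zero cell shift.
#' @export
parseOperatorTriplet <- function(triplet) {
    parts <- strsplit(gsub(" ", "", triplet), ",", fixed = TRUE)[[1]]
    if (length(parts) != 3L)
        stop("triplet must have three comma-separated components: ", triplet)
    rot <- matrix(0, 3, 3)
    trans <- numeric(3)
    for (i in 1:3) {
        expr <- parts[i]
        # tokenize into signed terms
        toks <- regmatches(expr,
            gregexpr("[+-]?[^+-]+", expr))[[1]]
        for (tok in toks) {
            sign <- if (startsWith(tok, "-")) -1 else 1
            body <- sub("^[+-]", "", tok)
            if (body %in% c("x", "y", "z")) {
                j <- match(body, c("x", "y", "z"))
                rot[i, j] <- rot[i, j] + sign
            } else if (grepl("^\\d+/\\d+$", body)) {
                nm <- as.numeric(strsplit(body, "/")[[1]])
                trans[i] <- trans[i] + sign * nm[1] / nm[2]
            } else if (grepl("^\\d*\\.?\\d+$", body)) {
                trans[i] <- trans[i] + sign * as.numeric(body)
            } else stop("cannot parse triplet term '", tok, "' in ", triplet)
        }
    }
    symOperator(rot, trans)
}

# Render a fractional translation component as triplet text ("", "+1/2", ...)
.fracText <- function(t) {
    t <- t - floor(t + 1e-9)
    if (abs(t) < 1e-6) return("")
    num <- round(t * 12)
    den <- 12
    g <- .gcd(num, den)
    paste0("+", num %/% g, "/", den %/% g)
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Write an operator in triplet notation
#'
#' The rotational part and the fractional part of the translation are
#' rendered as "x,y,z"-style text; whole-cell translations are returned
#' separately by \code{\link{operatorFingerprint}}.
#'
#' @param op A \linkS4class{SymOperator}.
#' @return Character(1), e.g. \code{"-x,y+1/2,-z"}.
#' @export
operatorTriplet <- function(op) {
    axes <- c("x", "y", "z")
    comps <- vapply(1:3, function(i) {
        terms <- ""
        for (j in 1:3) {
            cij <- round(op@rot[i, j])
            if (cij == 0) next
            sgn <- if (cij > 0) "+" else "-"
            terms <- paste0(terms, sgn, axes[j])
        }
        terms <- paste0(terms, .fracText(op@trans[i] + op@cellShift[i]))
        sub("^\\+", "", terms)
    }, character(1))
    paste(comps, collapse = ",")
}
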