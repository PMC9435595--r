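# Bundled operator table for the Sohncke space groups commonly seen in
# macromolecular crystals. Triplet strings follow International Tables
# conventions (general positions including centring copies). Short
# Hermann-Mauguin aliases are accepted by space_group().
.sg_table <- list(
  "P 1"        = c("x,y,z"),
  "P 1 2 1"    = c("x,y,z", "-x,y,-z"),
  "P 1 21 1"   = c("x,y,z", "-x,y+1/2,-z"),
  "C 1 2 1"    = c("x,y,z", "-x,y,-z", "x+1/2,y+1/2,z", "-x+1/2,y+1/2,-z"),
  "P 21 21 2"  = c("x,y,z", "-x,-y,z", "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z"),
  "P 21 21 21" = c("x,y,z", "-x+1/2,-y,z+1/2", "x+1/2,-y+1/2,-z", "-x,y+1/2,-z+1/2"),
  "C 2 2 21"   = c("x,y,z", "-x,-y,z+1/2", "x,-y,-z", "-x,y,-z+1/2",
                   "x+1/2,y+1/2,z", "-x+1/2,-y+1/2,z+1/2", "x+1/2,-y+1/2,-z", "-x+1/2,y+1/2,-z+1/2"),
  "P 41"       = c("x,y,z", "-y,x,z+1/4", "-x,-y,z+1/2", "y,-x,z+3/4"),
  "P 43"       = c("x,y,z", "-y,x,z+3/4", "-x,-y,z+1/2", "y,-x,z+1/4"),
  "P 41 21 2"  = c("x,y,z", "-y+1/2,x+1/2,z+1/4", "-x,-y,z+1/2", "y+1/2,-x+1/2,z+3/4",
                   "x+1/2,-y+1/2,-z+3/4", "-y,-x,-z+1/2", "-x+1/2,y+1/2,-z+1/4", "y,x,-z"),
  "P 43 21 2"  = c("x,y,z", "-y+1/2,x+1/2,z+3/4", "-x,-y,z+1/2", "y+1/2,-x+1/2,z+1/4",
                   "x+1/2,-y+1/2,-z+1/4", "-y,-x,-z+1/2", "-x+1/2,y+1/2,-z+3/4", "y,x,-z"),
  "P 31 2 1"   = c("x,y,z", "-y,x-y,z+1/3", "-x+y,-x,z+2/3", "y,x,-z",
                   "x-y,-y,-z+2/3", "-x,-x+y,-z+1/3"),
  "P 32 2 1"   = c("x,y,z", "-y,x-y,z+2/3", "-x+y,-x,z+1/3", "y,x,-z",
                   "x-y,-y,-z+1/3", "-x,-x+y,-z+2/3"),
  "P 61"       = c("x,y,z", "x-y,x,z+1/6", "-y,x-y,z+1/3", "-x,-y,z+1/2",
                   "-x+y,-x,z+2/3", "y,-x+y,z+5/6"),
  "P 65"       = c("x,y,z", "x-y,x,z+5/6", "-y,x-y,z+2/3", "-x,-y,z+1/2",
                   "-x+y,-x,z+1/3", "y,-x+y,z+1/6")
)

.sg_aliases <- c(
  "P1" = "P 1", "P2" = "P 1 2 1", "P21" = "P 1 21 1", "C2" = "C 1 2 1",
  "P21212" = "P 21 21 2", "P212121" = "P 21 21 21", "C2221" = "C 2 2 21",
  "P41" = "P 41", "P43" = "P 43", "P41212" = "P 41 21 2", "P43212" = "P 43 21 2",
  "P3121" = "P 31 2 1", "P3221" = "P 32 2 1", "P61" = "P 61", "P65" = "P 65"
)

.normalize_sg_symbol <- function(symbol) {
  sym <- toupper(gsub("[[:space:]]+", "", symbol))
  if (sym %in% names(.sg_aliases)) return(unname(.sg_aliases[sym]))
  full <- names(.sg_table)[toupper(gsub("[[:space:]]+", "", names(.sg_table))) == sym]
  if (length(full) == 1) return(full)
  NA_character_
}

# Parse a triplet like "-x,y+1/2,-z" into a rotation matrix (fractional
# basis) and a translation vector.
parse_symop_triplet <- function(triplet) {
  parts <- strsplit(gsub("[[:space:]]", "", tolower(triplet)), ",")[[1]]
  if (length(parts) != 3) stop("malformed symmetry triplet: ", triplet)
  R <- matrix(0, 3, 3)
  t <- numeric(3)
  for (i in 1:3) {
    expr <- parts[i]
    # tokenize into signed terms
    expr <- gsub("-", "+-", expr)
    terms <- strsplit(expr, "+", fixed = TRUE)[[1]]
    terms <- terms[nzchar(terms)]
    for (term in terms) {
      sign <- 1
      if (startsWith(term, "-")) { sign <- -1; term <- substring(term, 2) }
      if (term %in% c("x", "y", "z")) {
        R[i, match(term, c("x", "y", "z"))] <- sign
      } else if (grepl("^[0-9]+/[0-9]+$", term)) {
        fr <- as.numeric(strsplit(term, "/")[[1]])
        t[i] <- t[i] + sign * fr[1] / fr[2]
      } else if (grepl("^[0-9.]+$", term)) {
        t[i] <- t[i] + sign * as.numeric(term)
      } else stop("cannot parse symmetry term '", term, "' in ", triplet)
    }
  }
  symop(R, t)
}

#' Symmetry operation
#'
#' A space-group operation acting on fractional coordinates as
#' `R x + t`.
#'
#' @param R 3x3 rotation matrix in the fractional basis.
#' @param t Length-3 fractional translation.
#' @return Object of class `symop`.
#' @export
symop <- function(R, t = c(0, 0, 0)) {
  R <- matrix(as.numeric(R), 3, 3)
  d <- round(det(R))
  if (!d %in% c(-1, 1)) stop("symop rotation must have determinant +/-1")
  structure(list(R = R, t = as.numeric(t) %% 1), class = "symop")
}

#' @export
print.symop <- function(x, ...) {
  cat("<symop>", symop_triplet(x), "\n")
  invisible(x)
}

symop_triplet <- function(op) {
  axes <- c("x", "y", "z")
  comp <- character(3)
  for (i in 1:3) {
    s <- ""
    for (j in 1:3) {
      r <- op$R[i, j]
      if (r != 0) {
        pre <- if (r > 0 && nzchar(s)) "+" else if (r < 0) "-" else ""
        mag <- if (abs(r) == 1) "" else as.character(abs(r))
        s <- paste0(s, pre, mag, axes[j])
      }
    }
    tv <- op$t[i] %% 1
    if (abs(tv) > 1e-9) {
      fr <- round(tv * 12)
      g <- .gcd(fr, 12)
      s <- paste0(s, "+", fr %/% g, "/", 12 %/% g)
    }
    comp[i] <- s
  }
  paste(comp, collapse = ",")
}

.gcd <- function(a, b) if (b == 0) a else .gcd(b, a %% b)

#' Apply a symmetry operation to fractional positions
#'
#' @param op A [symop()].
#' @param pos Fractional position (length-3 vector or n x 3 matrix).
#' @param wrap If `TRUE`, wrap the result into `[0, 1)`.
#' @return Transformed fractional position(s).
#' @examples
#' op <- parse_symop("-x,y+1/2,-z")
#' apply_symop(op, c(0.10, 0.20, 0.30))
#' apply_symop(op, c(0.10, 0.20, 0.30), wrap = TRUE)
#' @export
apply_symop <- function(op, pos, wrap = FALSE) {
  if (is.matrix(pos)) {
    out <- t(op$R %*% t(pos)) + matrix(op$t, nrow(pos), 3, byrow = TRUE)
  } else {
    out <- as.numeric(op$R %*% pos + op$t)
  }
  if (wrap) out <- out %% 1
  out
}

#' Parse a symmetry-operation triplet string
#'
#' @param triplet A string such as `"-x,y+1/2,-z"`.
#' @return A [symop()].
#' @export
parse_symop <- function(triplet) parse_symop_triplet(triplet)

compose_symops <- function(a, b) {
  # (a o b)(x) = Ra (Rb x + tb) + ta
  symop(a$R %*% b$R, as.numeric(a$R %*% b$t + a$t))
}

invert_symop <- function(op) {
  Ri <- solve(op$R)
  symop(Ri, as.numeric(-Ri %*% op$t))
}

symops_equal <- function(a, b, tol = 1e-9) {
  max(abs(a$R - b$R)) < tol && max(abs(((a$t - b$t) %% 1 + 0.5) %% 1 - 0.5)) < tol
}

#' Space group
#'
#' Looks up a Hermann-Mauguin symbol in the bundled operator table (15
#' common Sohncke groups: P1, P2, P21, C2, P21212, P212121, C2221, P41,
#' P43, P41212, P43212, P3121, P3221, P61, P65). Short symbols such as
#' `"P212121"` and full symbols such as `"P 21 21 21"` are both accepted.
#'
#' @param symbol Hermann-Mauguin symbol.
#' @return Object of class `space_group` with elements `symbol` (full HM
#'   form) and `ops` (list of [symop()], identity first).
#' @export
space_group <- function(symbol) {
  full <- .normalize_sg_symbol(symbol)
  if (is.na(full))
    stop("unsupported space group symbol: ", symbol)
  ops <- lapply(.sg_table[[full]], parse_symop_triplet)
  structure(list(symbol = full, ops = ops), class = "space_group")
}

#' @export
print.space_group <- function(x, ...) {
  cat(sprintf("<space_group> %s (%d operations)\n", x$symbol, length(x$ops)))
  invisible(x)
}

sg_short_symbol <- function(sg) {
  nm <- names(.sg_aliases)[match(sg$symbol, .sg_aliases)]
  if (is.na(nm)) sg$symbol else nm
}

#' Candidate origin shifts for a space group
#'
#' Enumerates the translations that leave the space group invariant:
#' shifts `s` for which `(R - I) s` is a lattice translation for every
#' operation. On polar axes any shift component is allowed; those axes
#' are flagged continuous and the discrete component set to 0. Discrete
#' components are found by brute force over a 1/4-step lattice (the
#' translation subgroup of the Euclidean normalizer has components in
#' twelfths, but 1/4 steps cover all groups in the bundled table).
#'
#' @param sg A [space_group()].
#' @return List of origin shifts, each a list with fractional `shift`
#'   (length 3) and logical `continuous` (length 3).
#' @export
candidate_origin_shifts <- function(sg) {
  rots <- lapply(sg$ops, function(op) op$R)
  # axis e is continuous iff R e = e for every rotation
  continuous <- vapply(1:3, function(ax) {
    e <- numeric(3); e[ax] <- 1
    all(vapply(rots, function(R) max(abs(R %*% e - e)) < 1e-9, logical(1)))
  }, logical(1))
  shift_ok <- function(s) {
    for (op in sg$ops) {
      # conjugating (R, t) by translation s changes t by (R - I) s; the
      # result must be an operation of the group modulo lattice
      # translations.
      cand <- symop(op$R, op$t + as.numeric((op$R - diag(3)) %*% s))
      if (!any(vapply(sg$ops, function(o) symops_equal(o, cand), logical(1))))
        return(FALSE)
    }
    TRUE
  }
  steps <- c(0, 0.25, 0.5, 0.75)
  axis_vals <- lapply(1:3, function(ax) if (continuous[ax]) 0 else steps)
  grid <- expand.grid(u = axis_vals[[1]], v = axis_vals[[2]], w = axis_vals[[3]])
  shifts <- list()
  for (i in seq_len(nrow(grid))) {
    s <- as.numeric(grid[i, ])
    if (shift_ok(s))
      shifts[[length(shifts) + 1]] <- list(shift = s, continuous = continuous)
  }
  shifts
}
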