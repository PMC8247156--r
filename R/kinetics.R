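#' Convert specific activity to a turnover number
#'
#' kcat [1/h] = SA [umol/(mg min)] x MW [g/mol] x 60 [min/h] x 1e3 [mg/g]
#' x 1e-6 [mol/umol], i.e. a net factor of 0.06.
#'
#' @param sa specific activity, umol/(mg min).
#' @param mw molecular weight, g/mol (Da).
#' @return kcat in 1/h.
#' @export
sa_to_kcat <- function(sa, mw) {
  if (any(sa <= 0) || any(mw <= 0)) stop("sa and mw must be positive")
  sa * mw * 60 * 1e3 * 1e-6
}

#' Read a kcat evidence table
#'
#' TSV columns: \code{protein}, \code{reaction} (empty or "*" = wildcard,
#' applies to every reaction the protein catalyzes), \code{kcat_per_h},
#' \code{sa}, \code{mw_da}, \code{source}. Each row needs either a direct
#' kcat or both sa and mw.
#'
#' @param path TSV file.
#' @return data.frame of class \code{kcat_table}.
#' @export
read_kcat_table <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "reaction", "kcat_per_h", "sa", "mw_da", "source")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("kcat table missing columns: ",
                         paste(miss, collapse = ", "))
  as_kcat_table(d)
}

#' Construct a kcat table from a data.frame
#' @param d data.frame with the columns of \code{\link{read_kcat_table}}.
#' @return validated \code{kcat_table}.
#' @export
as_kcat_table <- function(d) {
  d$reaction[is.na(d$reaction) | d$reaction == ""] <- "*"
  has_kcat <- !is.na(d$kcat_per_h)
  has_sa <- !is.na(d$sa) & !is.na(d$mw_da)
  if (any(!has_kcat & !has_sa))
    stop("kcat record without kcat and without sa+mw (protein ",
         d$protein[which(!has_kcat & !has_sa)[1]], ")")
  if (any(d$kcat_per_h[has_kcat] <= 0) || any(d$sa[has_sa] <= 0) ||
      any(d$mw_da[has_sa] <= 0))
    stop("kinetic values must be positive")
  class(d) <- c("kcat_table", "data.frame")
  d
}

#' Select one kcat for a protein and reaction
#'
#' Resolution rule: among direct kcat entries the maximum wins; only when no
#' direct kcat exists is the maximum specific-activity conversion
#' (\code{\link{sa_to_kcat}}) used. Reaction-specific records beat wildcard
#' records. Provenance records which rule fired.
#'
#' @param table a \code{kcat_table}.
#' @param protein protein id.
#' @param rxn reaction id the value is for.
#' @return list(kcat, rule, source) or NULL when no evidence exists.
#' @export
select_kcat <- function(table, protein, rxn) {
  rec <- table[table$protein == protein &
               (table$reaction == rxn | table$reaction == "*"), , drop = FALSE]
  if (!nrow(rec)) return(NULL)
  specific <- rec[rec$reaction == rxn, , drop = FALSE]
  if (nrow(specific)) rec <- specific
  direct <- rec[!is.na(rec$kcat_per_h), , drop = FALSE]
  if (nrow(direct)) {
    i <- which.max(direct$kcat_per_h)
    return(list(kcat = direct$kcat_per_h[i], rule = "BRENDA-max",
                source = direct$source[i]))
  }
  kc <- sa_to_kcat(rec$sa, rec$mw_da)
  i <- which.max(kc)
  list(kcat = kc[i], rule = "SA-derived", source = rec$source[i])
}

#' Molecular weight of a protein from the kcat table
#' @param table a \code{kcat_table}.
#' @param protein protein id.
#' @return MW in g/mol, or NA if absent.
#' @export
protein_mw <- function(table, protein) {
  mw <- table$mw_da[table$protein == protein & !is.na(table$mw_da)]
  if (length(mw)) mw[1] else NA_real_
}

# ---------------------------------------------------------------------------
# Abundance evidence
# ---------------------------------------------------------------------------

#' Read a protein-abundance table
#'
#' TSV columns: \code{protein}, \code{abundance}, \code{unit} ("mmol_gDW" or
#' "ppm"), \code{taxon}, \code{rank} ("species", "genus", "family", "order",
#' "class" relative to the target organism). ppm values are converted with
#' \code{\link{ppm_to_mmol_gdw}} (requires \code{mw_da} column).
#'
#' @param path TSV file.
#' @param ptot total protein content used for ppm conversion, g protein/gDW.
#' @return data.frame of class \code{abundance_table} with canonical
#'   \code{abundance} in mmol/gDW.
#' @export
read_abundance_table <- function(path, ptot = 0.5) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein", "abundance", "unit", "taxon", "rank")
  miss <- setdiff(need, names(d))
  if (length(miss)) stop("abundance table missing columns: ",
                         paste(miss, collapse = ", "))
  is_ppm <- d$unit == "ppm"
  if (any(is_ppm)) {
    if (!"mw_da" %in% names(d))
      stop("ppm abundances need an mw_da column for conversion")
    d$abundance[is_ppm] <- ppm_to_mmol_gdw(d$abundance[is_ppm],
                                           d$mw_da[is_ppm], ptot)
    d$unit[is_ppm] <- "mmol_gDW"
  }
  as_abundance_table(d)
}

#' Construct an abundance table from a data.frame
#' @param d data.frame with columns \code{protein}, \code{abundance}
#'   (mmol/gDW), \code{taxon}, \code{rank}.
#' @return validated \code{abundance_table}.
#' @export
as_abundance_table <- function(d) {
  if (any(d$abundance < 0)) stop("abundance must be >= 0")
  ranks <- c("species", "genus", "family", "order", "class")
  if (any(!d$rank %in% ranks))
    stop("unknown rank: ", d$rank[!d$rank %in% ranks][1])
  class(d) <- c("abundance_table", "data.frame")
  d
}

#' Convert a PAXdb-style ppm abundance to mmol/gDW
#'
#' abundance = ppm x 1e-6 x Ptot / MW x 1e3, with Ptot the total protein
#' content (g protein/gDW; default 0.5) and MW in g/mol.
#'
#' @param ppm parts-per-million abundance.
#' @param mw molecular weight, g/mol.
#' @param ptot total protein content, g/gDW.
#' @return abundance in mmol/gDW.
#' @export
ppm_to_mmol_gdw <- function(ppm, mw, ptot = 0.5) {
  ppm * 1e-6 * ptot / mw * 1e3
}

#' Match an abundance bound for a protein with taxonomic fallback
#'
#' Species-level entries win when present (their maximum). Otherwise ranks
#' are scanned in the order genus, family, order, class, and the maximum at
#' the FIRST rank holding any entry is returned. No entry at any rank means
#' no constraint (the enzyme is left unconstrained downstream).
#'
#' @param table an \code{abundance_table}.
#' @param protein protein id.
#' @return list(abundance, taxon, rank) or NULL.
#' @export
match_abundance <- function(table, protein) {
  rec <- table[table$protein == protein, , drop = FALSE]
  if (!nrow(rec)) return(NULL)
  for (rk in c("species", "genus", "family", "order", "class")) {
    at <- rec[rec$rank == rk, , drop = FALSE]
    if (nrow(at)) {
      i <- which.max(at$abundance)
      return(list(abundance = at$abundance[i], taxon = at$taxon[i], rank = rk))
    }
  }
  NULL
}
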