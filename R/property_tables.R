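DNA_BASES <- c("A", "C", "G", "T")

all_kmers <- function(order) {
  stopifnot(order >= 1)
  km <- DNA_BASES
  for (i in seq_len(order - 1)) {
    km <- as.vector(outer(km, DNA_BASES, paste0))
  }
  sort(km)
}

#' Construct a structural-property lookup table
#'
#' A property table maps every k-mer over \{A, C, G, T\} (k = 2 for
#' dinucleotide properties, k = 3 for trinucleotide properties) to a real
#' value describing a local physicochemical or conformational property of
#' the DNA duplex, e.g. base-stacking energy in kcal/mole.
#'
#' @param name Short identifier for the property (e.g. `"base_stack_energy"`).
#' @param order Integer k-mer length, 2 or 3.
#' @param values Named numeric vector with exactly `4^order` entries, one per
#'   k-mer; names are uppercased on construction.
#' @param units Free-text unit annotation (e.g. `"kcal/mole"`).
#' @return An object of class `property_table` with fields `name`, `order`,
#'   `values` (sorted by k-mer) and `units`.
#' @examples
#' vals <- setNames(rep(0, 16), promstruct:::all_kmers(2))
#' property_table("flat", 2, vals)
#' @export
property_table <- function(name, order, values, units = "") {
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("'name' must be a non-empty string")
  }
  order <- as.integer(order)
  if (!(order %in% c(2L, 3L))) {
    stop("'order' must be 2 (dinucleotide) or 3 (trinucleotide)")
  }
  if (is.null(names(values))) stop("'values' must be a named numeric vector")
  names(values) <- toupper(names(values))
  expected <- all_kmers(order)
  bad_len <- names(values)[nchar(names(values)) != order]
  if (length(bad_len)) {
    stop(sprintf("k-mer length does not match order %d: %s",
                 order, paste(bad_len, collapse = ", ")))
  }
  dup <- unique(names(values)[duplicated(names(values))])
  if (length(dup)) {
    stop(sprintf("duplicate k-mer(s): %s", paste(dup, collapse = ", ")))
  }
  missing <- setdiff(expected, names(values))
  if (length(missing)) {
    stop(sprintf("missing k-mer(s): %s", paste(missing, collapse = ", ")))
  }
  extra <- setdiff(names(values), expected)
  if (length(extra)) {
    stop(sprintf("unexpected k-mer(s) outside the ACGT alphabet: %s",
                 paste(extra, collapse = ", ")))
  }
  if (!all(is.finite(values))) {
    stop("all property values must be finite")
  }
  structure(
    list(name = name, order = order,
         values = values[expected], units = units),
    class = "property_table"
  )
}

#' @export
print.property_table <- function(x, ...) {
  cat(sprintf("<property_table> %s (order %d%s): %d k-mers, range [%g, %g]\n",
              x$name, x$order,
              if (nzchar(x$units)) paste0(", ", x$units) else "",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' Read a property table from a two-column text file
#'
#' The file dialect is two whitespace/tab-separated columns (k-mer, value);
#' `#` starts a comment; an optional header line (non-numeric second column)
#' is skipped.
#'
#' @param file Path or connection to the table file.
#' @param name Property identifier; defaults to the file's base name.
#' @param order Expected k-mer length; inferred from the first k-mer when
#'   `NULL`, and validated against every row either way.
#' @param units Unit annotation carried on the returned table.
#' @return A [property_table()].
#' @export
read_property_table <- function(file, name = NULL, order = NULL, units = "") {
  if (is.null(name)) {
    name <- sub("\\.(synthetic\\.)?(tsv|txt)$", "", basename(file))
  }
  lines <- readLines(file)
  lines <- sub("#.*$", "", lines)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stop("no data rows in property table file")
  fields <- strsplit(trimws(lines[keep]), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf != 2)) {
    stop(sprintf("expected 2 columns, got %d at line %d",
                 nf[which(nf != 2)[1]], keep[which(nf != 2)[1]]))
  }
  km <- toupper(vapply(fields, `[`, "", 1))
  raw <- vapply(fields, `[`, "", 2)
  # optional header: first row with a non-numeric value column
  vals <- suppressWarnings(as.numeric(raw))
  if (is.na(vals[1]) && !is.na(suppressWarnings(as.numeric(raw[2])))) {
    km <- km[-1]; raw <- raw[-1]; vals <- vals[-1]; keep <- keep[-1]
  }
  bad <- which(is.na(vals))
  if (length(bad)) {
    stop(sprintf("non-numeric value '%s' at line %d", raw[bad[1]], keep[bad[1]]))
  }
  if (is.null(order)) order <- nchar(km[1])
  property_table(name, order, stats::setNames(vals, km), units)
}

#' Write a property table to a two-column text file
#'
#' Values are printed with [format()] at full precision (15 significant
#' digits), so `read_property_table(write_property_table(t))` round-trips
#' the table exactly as printed.
#'
#' @param table A [property_table()].
#' @param file Path or writable connection.
#' @return `file`, invisibly.
#' @export
write_property_table <- function(table, file) {
  stopifnot(inherits(table, "property_table"))
  hdr <- sprintf("# %s%s (order %d)", table$name,
                 if (nzchar(table$units)) paste0(" (", table$units, ")") else "",
                 table$order)
  rows <- sprintf("%s\t%s", names(table$values),
                  format(table$values, digits = 15, trim = TRUE,
                         scientific = FALSE))
  writeLines(c(hdr, rows), file)
  invisible(file)
}

# canonical 13-property set; bendability and nucleosome positioning are the
# two trinucleotide scales, the rest are dinucleotide scales
CANONICAL_PROPERTIES <- data.frame(
  name = c("a_philicity", "base_stack_energy", "b_dna", "bendability",
           "dna_bending_stiffness", "disrupt_energy", "dna_denaturation",
           "free_energy", "nucleosome_positioning", "propeller_twist",
           "protein_deformation", "protein_dna_twist", "z_dna"),
  order = c(2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L, 3L, 2L, 2L, 2L, 2L),
  stringsAsFactors = FALSE
)

#' Construct a property registry
#'
#' A registry is an ordered collection of property tables; the ordering fixes
#' the feature layout used by [encode_features()].
#'
#' @param tables List of [property_table()] objects with unique names.
#' @return An object of class `property_registry`.
#' @export
property_registry <- function(tables) {
  if (!length(tables) || !all(vapply(tables, inherits, TRUE, "property_table"))) {
    stop("'tables' must be a non-empty list of property_table objects")
  }
  nms <- vapply(tables, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop("property names must be unique")
  }
  structure(list(tables = stats::setNames(tables, nms)),
            class = "property_registry")
}

#' @export
print.property_registry <- function(x, ...) {
  cat(sprintf("<property_registry> %d properties (%d dinucleotide, %d trinucleotide)\n",
              length(x$tables),
              sum(registry_orders(x) == 2), sum(registry_orders(x) == 3)))
  for (t in x$tables) cat(sprintf("  %-24s order %d\n", t$name, t$order))
  invisible(x)
}

#' @export
length.property_registry <- function(x) length(x$tables)

registry_orders <- function(registry) {
  vapply(registry$tables, `[[`, 1L, "order")
}

.registry_cache <- new.env(parent = emptyenv())

#' The canonical 13-property registry
#'
#' Returns the bundled registry of the 13 structural properties used for
#' sequence characterization: A-philicity, base stack energy, B-DNA,
#' bendability, DNA-bending stiffness, disrupt energy, DNA denaturation,
#' free energy, nucleosome positioning, propeller twist, protein
#' deformation, protein-DNA twist and Z-DNA. Bendability and nucleosome
#' positioning are trinucleotide scales; the remaining 11 are dinucleotide
#' scales, so a window of L nucleotides encodes to
#' `11 * (L - 1) + 2 * (L - 2)` features.
#'
#' Only the base-stacking-energy table reproduces published values exactly;
#' the other 12 bundled files are synthetic stand-ins (realistic range,
#' reverse-complement symmetric) and are labelled as such both in their file
#' names and in their headers.
#'
#' @return A [property_registry()] with 13 entries in canonical order.
#' @examples
#' reg <- builtin_registry()
#' length(reg)
#' @export
builtin_registry <- function() {
  if (!is.null(.registry_cache$builtin)) return(.registry_cache$builtin)
  dir <- system.file("extdata", "properties", package = "promstruct")
  if (!nzchar(dir)) stop("bundled property tables not found")
  tables <- lapply(seq_len(nrow(CANONICAL_PROPERTIES)), function(i) {
    nm <- CANONICAL_PROPERTIES$name[i]
    path <- file.path(dir, paste0(nm, ".tsv"))
    if (!file.exists(path)) path <- file.path(dir, paste0(nm, ".synthetic.tsv"))
    if (!file.exists(path)) stop(sprintf("bundled table missing: %s", nm))
    tab <- read_property_table(path, name = nm)
    if (tab$order != CANONICAL_PROPERTIES$order[i]) {
      stop(sprintf("bundled table %s has order %d, expected %d",
                   nm, tab$order, CANONICAL_PROPERTIES$order[i]))
    }
    tab
  })
  reg <- property_registry(tables)
  if (length(reg) != 13L) stop("canonical registry must have 13 entries")
  .registry_cache$builtin <- reg
  reg
}
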