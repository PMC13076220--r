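# Functional-group classification of high-rank soil animal taxa.

.default_group_entries <- c(
  # herbivores: root and plant feeders
  Hemiptera = "herbivore", Orthoptera = "herbivore",
  Thysanoptera = "herbivore", Lepidoptera = "herbivore",
  # detritivores: primary decomposers of dead plant material
  Lumbricina = "detritivore", Diplopoda = "detritivore",
  Isopoda = "detritivore", Isoptera = "detritivore",
  Dermaptera = "detritivore", Blattodea = "detritivore",
  Gastropoda = "detritivore", Enchytraeidae = "detritivore",
  # microbivores: secondary decomposers feeding on fungi and prokaryotes
  Collembola = "microbivore", Oribatida = "microbivore",
  Nematoda = "microbivore", Protura = "microbivore",
  Prostigmata = "microbivore", Psocoptera = "microbivore",
  Symphyla = "microbivore",
  # predators
  Araneae = "predator", Chilopoda = "predator", Diplura = "predator",
  Formicidae = "predator", Mesostigmata = "predator",
  Opiliones = "predator", Pseudoscorpiones = "predator",
  # mixed feeders
  Diptera = "mixed", Coleoptera = "mixed"
)

.default_aliases <- c(Mesotigmata = "Mesostigmata")

#' Construct a taxon-to-functional-group map
#'
#' A group map assigns each high-rank taxon name to exactly one of the five
#' trophic functional groups of soil fauna: herbivore, detritivore,
#' microbivore, predator or mixed feeder. Lookups are case-insensitive and
#' whitespace-trimmed; `aliases` declares alternative spellings that resolve
#' to a canonical taxon name before lookup.
#'
#' @param entries Named character vector, taxon name -> functional group.
#' @param aliases Named character vector, alias spelling -> canonical taxon.
#' @return An object of class `group_map`.
#' @seealso [default_group_map()], [assign_functional_group()]
#' @export
group_map <- function(entries, aliases = character()) {
  if (is.null(names(entries)) || any(!nzchar(names(entries))))
    stop("every group-map entry must be named by a taxon", call. = FALSE)
  if (anyDuplicated(tolower(trimws(names(entries)))))
    stop("each taxon must map to exactly one functional group", call. = FALSE)
  bad <- setdiff(unique(entries), functional_group_levels)
  if (length(bad))
    stop("unknown functional group(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (length(aliases)) {
    missing_target <- setdiff(tolower(aliases), tolower(names(entries)))
    if (length(missing_target))
      stop("alias target(s) not in the map: ",
           paste(missing_target, collapse = ", "), call. = FALSE)
  }
  structure(list(entries = entries, aliases = aliases), class = "group_map")
}

#' Default functional-group classification of soil animal taxa
#'
#' Returns the built-in classification of 28 high-rank soil animal taxa into
#' five functional groups: herbivores (Hemiptera, Orthoptera, Thysanoptera,
#' Lepidoptera), detritivores (Lumbricina, Diplopoda, Isopoda, Isoptera,
#' Dermaptera, Blattodea, Gastropoda, Enchytraeidae), microbivores
#' (Collembola, Oribatida, Nematoda, Protura, Prostigmata, Psocoptera,
#' Symphyla), predators (Araneae, Chilopoda, Diplura, Formicidae,
#' Mesostigmata, Opiliones, Pseudoscorpiones) and mixed feeders (Diptera,
#' Coleoptera). "Mesotigmata" is registered as a spelling alias of
#' Mesostigmata.
#'
#' @param extra Optional named character vector of additional
#'   taxon -> group entries (e.g. `c(Tardigrada = "predator")`).
#' @param aliases Optional additional alias spellings.
#' @return A `group_map`.
#' @export
#' @examples
#' assign_functional_group("Collembola", default_group_map())
default_group_map <- function(extra = character(), aliases = character()) {
  group_map(c(.default_group_entries, extra),
            c(.default_aliases, aliases))
}

#' @export
print.group_map <- function(x, ...) {
  tab <- table(factor(x$entries, levels = functional_group_levels))
  cat("<group_map> ", length(x$entries), " taxa, ",
      length(x$aliases), " alias(es)\n", sep = "")
  print(tab)
  invisible(x)
}

#' Look up the functional group of a taxon
#'
#' Matching is case-insensitive and ignores surrounding whitespace; declared
#' alias spellings are resolved first. Unknown taxa raise an error carrying
#' the offending name (use [read_records()] in lenient mode to drop them
#' instead).
#'
#' @param taxon Character vector of high-rank taxon names.
#' @param map A `group_map`, by default [default_group_map()].
#' @return Character vector of functional groups, same length as `taxon`.
#' @export
#' @examples
#' assign_functional_group(c("Araneae", " collembola "))
assign_functional_group <- function(taxon, map = default_group_map()) {
  stopifnot(inherits(map, "group_map"))
  key <- tolower(trimws(taxon))
  if (length(map$aliases)) {
    idx <- match(key, tolower(names(map$aliases)))
    hit <- !is.na(idx)
    key[hit] <- tolower(map$aliases[idx[hit]])
  }
  pos <- match(key, tolower(names(map$entries)))
  if (anyNA(pos)) {
    unknown <- unique(taxon[is.na(pos)])
    stop("taxon not in functional-group map: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  unname(map$entries[pos])
}

#' Taxa registered for one functional group
#'
#' @param group One of `"herbivore"`, `"detritivore"`, `"microbivore"`,
#'   `"predator"`, `"mixed"`.
#' @param map A `group_map`.
#' @return Character vector of taxon names.
#' @export
group_taxa <- function(group, map = default_group_map()) {
  group <- match.arg(group, functional_group_levels)
  names(map$entries)[map$entries == group]
}
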