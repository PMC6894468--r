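#' Activity taxonomies
#'
#' An activity taxonomy maps fine-grained diary activity codes to a small
#' set of everyday activity domains, and optionally to sub-domains within
#' one domain (in the packaged default, six Exercise and Sport sub-domains).
#' Domains listed in \code{excluded_from_pa} are kept in the everyday-domain
#' analysis but excluded from the physical-activity view (the default
#' excludes Active Transport, which is dominated by low-intensity walking).
#'
#' @param activity_map data.frame with columns \code{activity_code},
#'   \code{domain} and optionally \code{subdomain} (NA where a code has no
#'   sub-domain).
#' @param excluded_from_pa character vector of domain labels excluded from
#'   the physical-activity analysis.
#' @return An object of class \code{activity_taxonomy}.
#' @export
activity_taxonomy <- function(activity_map, excluded_from_pa = character()) {
  stopifnot(is.data.frame(activity_map))
  required <- c("activity_code", "domain")
  missing <- setdiff(required, names(activity_map))
  if (length(missing)) {
    stop("taxonomy is missing column(s): ", paste(missing, collapse = ", "))
  }
  if (!"subdomain" %in% names(activity_map)) activity_map$subdomain <- NA_character_
  activity_map$activity_code <- as.character(activity_map$activity_code)
  activity_map$domain <- as.character(activity_map$domain)
  activity_map$subdomain <- as.character(activity_map$subdomain)
  dup <- unique(activity_map$activity_code[duplicated(activity_map$activity_code)])
  if (length(dup)) {
    stop("activity code(s) mapped more than once: ", paste(dup, collapse = ", "))
  }
  bad <- setdiff(excluded_from_pa, activity_map$domain)
  if (length(bad)) {
    stop("excluded_from_pa names unknown domain(s): ", paste(bad, collapse = ", "))
  }
  structure(
    list(
      activity_map = activity_map[, c("activity_code", "domain", "subdomain")],
      excluded_from_pa = excluded_from_pa
    ),
    class = "activity_taxonomy"
  )
}

#' @export
print.activity_taxonomy <- function(x, ...) {
  cat("Activity taxonomy:", nrow(x$activity_map), "codes,",
      length(domains(x)), "domains,",
      length(subdomains(x)), "sub-domains\n")
  if (length(x$excluded_from_pa)) {
    cat("Excluded from physical-activity analysis:",
        paste(x$excluded_from_pa, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Domain and sub-domain labels of a taxonomy
#'
#' @param taxonomy an \code{activity_taxonomy}.
#' @return Character vector of unique domain (resp. sub-domain) labels, in
#'   first-appearance order.
#' @export
domains <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "activity_taxonomy"))
  unique(taxonomy$activity_map$domain)
}

#' @rdname domains
#' @export
subdomains <- function(taxonomy) {
  stopifnot(inherits(taxonomy, "activity_taxonomy"))
  s <- taxonomy$activity_map$subdomain
  unique(s[!is.na(s)])
}

#' Read a taxonomy from a delimited mapping file
#'
#' The file is a two-column delimited mapping from activity code to domain,
#' where the domain field may carry a sub-domain after a forward slash
#' (\code{"Exercise and Sport/Team Sports"}). Comment lines starting with
#' \code{#} are ignored; comma or tab separation is auto-detected.
#'
#' @param path path to the mapping file.
#' @param excluded_from_pa domains excluded from the physical-activity view.
#' @return An \code{activity_taxonomy}.
#' @export
read_taxonomy <- function(path, excluded_from_pa = character()) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  raw <- read_delim_auto(path)
  missing <- setdiff(c("activity_code", "domain"), names(raw))
  if (length(missing)) {
    stop("taxonomy file is missing column(s): ", paste(missing, collapse = ", "))
  }
  parts <- strsplit(as.character(raw$domain), "/", fixed = TRUE)
  map <- data.frame(
    activity_code = as.character(raw$activity_code),
    domain = vapply(parts, `[`, character(1), 1L),
    subdomain = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_,
                       character(1)),
    stringsAsFactors = FALSE
  )
  activity_taxonomy(map, excluded_from_pa = excluded_from_pa)
}

#' The packaged default taxonomy
#'
#' Eleven everyday activity domains (Sleep, Self-care, Social, Cultural,
#' Screen Time, Chores, Work and Study, Quiet Time, Active Transport,
#' Passive Transport, Exercise and Sport) with six Exercise and Sport
#' sub-domains (Non-Team Sports, Team Sports, Gym, Dance, Active Play,
#' Games). Active Transport is excluded from the physical-activity view.
#'
#' @return An \code{activity_taxonomy}.
#' @export
default_taxonomy <- function() {
  path <- system.file("extdata", "default_taxonomy.tsv", package = "dupbehav",
                      mustWork = TRUE)
  read_taxonomy(path, excluded_from_pa = "Active Transport")
}

# map activity codes to domain or subdomain labels; unknown codes -> error
map_activities <- function(codes, taxonomy, level = c("domain", "subdomain")) {
  level <- match.arg(level)
  map <- taxonomy$activity_map
  idx <- match(codes, map$activity_code)
  if (anyNA(idx)) {
    bad <- sort(unique(codes[is.na(idx)]))
    stop("activity code(s) not in taxonomy: ", paste(bad, collapse = ", "))
  }
  if (level == "domain") map$domain[idx] else map$subdomain[idx]
}
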