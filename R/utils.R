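# shared internal helpers

# read a comma- or tab-delimited file with auto-detection and # comments
read_delim_auto <- function(path) {
  lines <- readLines(path, n = 50L, warn = FALSE)
  lines <- lines[!startsWith(trimws(lines), "#") & nzchar(trimws(lines))]
  if (!length(lines)) stop("no data lines in file: ", path)
  sep <- if (lengths(regmatches(lines[1], gregexpr("\t", lines[1]))) > 0) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE,
                    quote = "\"", na.strings = c("NA", ""))
}

# order activity labels by descending penetration, ties alphabetical
order_by_penetration <- function(penetration) {
  order(-penetration, names(penetration), method = "radix")
}

round_display <- function(x, digits) {
  # round-half-away-from-zero, the convention of printed summary tables
  sign(x) * floor(abs(x) * 10^digits + 0.5) / 10^digits
}
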