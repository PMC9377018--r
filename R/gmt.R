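#' Gene-set collections (GMT-backed)
#'
#' A named collection of gene sets, each with a free-text description and a
#' deduplicated vector of member gene symbols.
#'
#' @param sets Named list; each element is `list(description =, genes =)` or
#'   simply a character vector of genes.
#' @return A `gene_set_collection`.
#' @export
gene_set_collection <- function(sets) {
  if (is.null(names(sets)) || anyDuplicated(names(sets))) {
    abort("Set names must be present and unique.")
  }
  sets <- lapply(sets, function(s) {
    if (is.character(s)) s <- list(description = "", genes = s)
    s$genes <- unique(s$genes)
    if (!length(s$genes)) abort("Each set must be non-empty.")
    s
  })
  structure(list(sets = sets), class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
names.gene_set_collection <- function(x) names(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("<gene_set_collection> %d sets, %d distinct genes\n",
              length(x$sets),
              length(unique(unlist(lapply(x$sets, `[[`, "genes"))))))
  invisible(x)
}

#' @describeIn gene_set_collection Tidy into a (set, description, gene) tibble.
#' @param x A `gene_set_collection`.
#' @param ... Unused.
#' @method tidy gene_set_collection
#' @export
tidy.gene_set_collection <- function(x, ...) {
  purrr::imap_dfr(x$sets, function(s, nm) {
    tibble(set = nm, description = s$description, gene = s$genes)
  })
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes within a
#' set are stored once.
#'
#' @param path GMT file.
#' @return A [gene_set_collection()].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  sets <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) {
      abort(sprintf("GMT line %d has %d field(s); at least 3 required.",
                    i, length(f)))
    }
    sets[[f[1]]] <- list(description = f[2], genes = unique(f[-(1:2)]))
  }
  gene_set_collection(sets)
}

#' Write a GMT gene-set file
#' @param x A [gene_set_collection()].
#' @param path Output file.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- purrr::imap_chr(x$sets, function(s, nm) {
    paste(c(nm, s$description, s$genes), collapse = "\t")
  })
  writeLines(lines, path)
  invisible(path)
}
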