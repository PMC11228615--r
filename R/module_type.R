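# Module-type classification from domain composition.

.KR_CANONICAL_DOMAINS <- c("KS", "AT", "DH", "ER", "KR", "ACP")

.KR_MODULE_ARCHITECTURES <- list(
  alpha = c("KS", "AT", "ACP"),
  beta  = c("KS", "AT", "KR", "ACP"),
  gamma = c("KS", "AT", "DH", "KR", "ACP"),
  delta = c("KS", "AT", "DH", "ER", "KR", "ACP")
)

#' Classify a PKS module by its domain composition
#'
#' Modules of cis-AT PKSs are typed purely by which beta-processing domains
#' accompany the KS-AT-ACP core, in canonical N-to-C order and regardless of
#' whether those domains are catalytically active: KS-AT-ACP is an
#' alpha-module, adding KR gives beta, adding DH+KR gamma, and DH+ER+KR
#' delta.  Any other arrangement (duplicated KRs, missing KS, ER without DH,
#' domains out of canonical order) is reported as \code{unconventional}.
#' Auxiliary domains outside the canonical six (e.g. methyltransferases)
#' are ignored for typing and returned in the \code{extras} attribute.
#'
#' @param domains Character vector of domain codes in N-to-C order, or a
#'   single comma-separated string (e.g. \code{"KS,AT,DH,KR,ACP"}).
#' @return One of \code{"alpha"}, \code{"beta"}, \code{"gamma"},
#'   \code{"delta"}, \code{"unconventional"}, with attribute
#'   \code{extras} listing any ignored auxiliary codes.
#' @examples
#' classify_module(c("KS", "AT", "KR", "ACP"))       # beta
#' classify_module("KS,AT,DH,ER,KR,ACP")             # delta
#' classify_module(c("KS", "AT", "MT", "KR", "ACP")) # beta, MT ignored
#' @export
classify_module <- function(domains) {
  if (length(domains) == 1L && grepl(",", domains))
    domains <- strsplit(domains, ",")[[1]]
  domains <- unname(trimws(toupper(domains)))
  domains <- domains[nzchar(domains)]
  if (length(domains) == 0L)
    stop("empty domain list", call. = FALSE)

  core <- domains[domains %in% .KR_CANONICAL_DOMAINS]
  extras <- unique(domains[!domains %in% .KR_CANONICAL_DOMAINS])

  type <- "unconventional"
  for (nm in names(.KR_MODULE_ARCHITECTURES)) {
    if (identical(core, .KR_MODULE_ARCHITECTURES[[nm]])) {
      type <- nm
      break
    }
  }
  structure(type, extras = extras)
}

# vectorized helper over comma-separated strings, attribute-free
.classify_modules <- function(domain_strings) {
  vapply(domain_strings,
         function(d) as.character(classify_module(d)),
         character(1), USE.NAMES = FALSE)
}
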