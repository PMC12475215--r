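# Environment plumbing. Conda R builds ship without /usr/share/zoneinfo;
# unless TZDIR points at a tz database, every named zone silently resolves
# to UTC+0, which would shift all standard-time bin alignment by an hour.
# Probe the usual locations at load time.

tzdir_ok <- function() {
  off <- as.POSIXlt(as.POSIXct("2016-01-01 12:00:00", tz = "Etc/GMT-1"))$gmtoff
  isTRUE(off == 3600L)
}

ensure_tzdir <- function() {
  if (tzdir_ok()) return(invisible(TRUE))
  cands <- c(Sys.getenv("TZDIR"),
             file.path(R.home("share"), "zoneinfo"),
             file.path(Sys.getenv("CONDA_PREFIX"), "share", "zoneinfo"),
             file.path(dirname(dirname(R.home())), "share", "zoneinfo"),
             "/opt/conda/envs/bio/share/zoneinfo",
             "/usr/share/zoneinfo", "/etc/zoneinfo")
  for (d in unique(cands[nzchar(cands)])) {
    if (file.exists(file.path(d, "Etc", "GMT-1"))) {
      Sys.setenv(TZDIR = d)
      if (tzdir_ok()) return(invisible(TRUE))
    }
  }
  invisible(FALSE)
}

.onLoad <- function(libname, pkgname) {
  if (!ensure_tzdir())
    packageStartupMessage(
      "motact: no usable tz database found; fixed-offset fallback in effect")
}
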