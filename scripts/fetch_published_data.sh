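#!/usr/bin/env bash
# Optional helper: download the published datasets behind the full-scale
# numbers (never required by the package, its tests, or the acceptance
# script; requires network access).
#
#   GEO GSE19836            120 overexpression arrays (mES cell bank)
#   ArrayExpress E-MEXP-654 transchromosomic Tc1 vs control arrays
#   World-2DPAGE 0021       Runx1 2DGE spot quantification
#
# Usage: scripts/fetch_published_data.sh <output-dir>

set -euo pipefail
out="${1:-data-published}"
mkdir -p "$out"

echo "Fetching GEO series matrix for GSE19836..."
curl -fL --retry 3 -o "$out/GSE19836_series_matrix.txt.gz" \
  "https://ftp.ncbi.nlm.nih.gov/geo/series/GSE19nnn/GSE19836/matrix/GSE19836_series_matrix.txt.gz"

echo "Fetching ArrayExpress E-MEXP-654 processed data..."
curl -fL --retry 3 -o "$out/E-MEXP-654.processed.zip" \
  "https://www.ebi.ac.uk/biostudies/files/E-MEXP-654/E-MEXP-654.processed.1.zip"

echo "World-2DPAGE accession 0021 is browsable at:"
echo "  https://world-2dpage.expasy.org/repository/0021/"
echo "Done. Files in $out/"
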