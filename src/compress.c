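/* Size-only LZMA2 (xz container) compression via liblzma, with preset
 * control. Only the compressed length is needed for NCD, so the output
 * buffer is scratch. */

#include <R.h>
#include <Rinternals.h>
#include <R_ext/Rdynload.h>
#include <lzma.h>

SEXP C_xz_compressed_size(SEXP raw, SEXP preset_)
{
    if (TYPEOF(raw) != RAWSXP) error("input must be a raw vector");
    R_xlen_t n = XLENGTH(raw);
    if (n == 0) error("cannot compress an empty byte sequence");
    uint32_t preset = (uint32_t) asInteger(preset_);
    if (preset > 9) error("preset must be in 0..9");

    size_t cap = lzma_stream_buffer_bound((size_t) n);
    unsigned char *out = (unsigned char *) R_alloc(cap, 1);
    size_t out_pos = 0;

    lzma_ret rc = lzma_easy_buffer_encode(preset, LZMA_CHECK_NONE, NULL,
                                          RAW(raw), (size_t) n,
                                          out, &out_pos, cap);
    if (rc != LZMA_OK) error("liblzma encoding failed (code %d)", (int) rc);
    return ScalarInteger((int) out_pos);
}

static const R_CallMethodDef call_entries[] = {
    {"C_xz_compressed_size", (DL_FUNC) &C_xz_compressed_size, 2},
    {NULL, NULL, 0}
};

void R_init_infodyn(DllInfo *dll)
{
    R_registerRoutines(dll, NULL, call_entries, NULL, NULL);
    R_useDynamicSymbols(dll, FALSE);
}
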