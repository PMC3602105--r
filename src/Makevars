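# lzma.h is not shipped inside every R installation's include path;
# -idirafter keeps the toolchain's own system headers first.
PKG_CPPFLAGS = -idirafter /usr/include
PKG_LIBS = -L/usr/lib/x86_64-linux-gnu -llzma
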