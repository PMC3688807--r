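# pd2loop rama_map v1 cell=10 provenance=75 training structures
AFFFFFFFFFFFFFFFFFFFFFFFFFFFAAAAAAAA
AAAFFFFFFFFFFFFFFFFFFFFFFAAAAAAAAAAA
AAAFFFFFFFFFFFFFFFFFFFFFFAAAAAAAAAAA
AAAFFFFFFFFFFFFFFFAAAAAFFAAAAAAAAAAA
AAAFFFFFFFFFFFAAAAAAAAAFFAAAAAAAAAAA
AAAFFFFFFFFAAAAAAAAAAAAFFAAAAAAAAAAA
AAAFFFFFFFFAAAAAAAAAAAAFFFAAAAAAAAAA
AAFFFFFFFFAAAAAAAAAAAAAFFFAAAAAAAAAA
AFFFFFFFFFAAAAAAAAAAAAAFFFAAAAAAAAAA
AAFFFFFFFAAAAAAAAAAAAAAFFFAAAAAAAAAA
AAFFFFFFAAAAAAAAAAAAAAAFFFAAAAAAAAAA
AAFFFFFFAAAAAAAAAAAAAAFFFFAAAAAAAAAA
AAFFFFFFAAAAAAAAAAAAAFFFFFAAAAAAAAAA
AAFFFFFFAAAAAAAAAAAAFFFFFFAAAAAAAAAA
AFFFFFFFAAAAAAAAAAAFFFFFFFAAAAAAAAAA
FFFFFFFFAAAAAAAAAAAFFFFFFFAAAAAAAAFF
FFFFFFFFAAAAAAAAAAAFFFFFFFFFFFFFFFFF
FFFFFFFFAAAAAAAAAFFFFFFFFFFFFFFFFFFF
FFFFFFFFFFAAAAAFFFFFFFFFFFFFFFFFFFFF
FFFFFFFFFFFFFFFFFFFAAAAAFFFFFFFFFFFF
FFFFFFFFFFFFFFFFFFFAAAAAAAAFFFFFFFFF
FFFFFFFFFFFFFFFFFFAAAAAAAAAFFFFFFFFF
FFFFFFFFFFFFFFFFFFAAAAAAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFAAAAAAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFAAAAAAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFAAAAAAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFAAAAAAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFAAAAAAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFFAAAAAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFFFFAAAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFFFFFFAAAAAFFFFFFFF
FFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFF
FFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFF
FFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFF
FFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFFF
AFFFFFFFFFFFFFFFFFFFFFFFFFFFAAAAAAAA
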