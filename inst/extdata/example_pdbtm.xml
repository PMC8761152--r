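<?xml version="1.0" encoding="UTF-8"?>
<!-- Experimental membrane-thickness dialect read by parse_pdbtm_thickness():
     one <entry> per deposited structure; <half_thickness> is the fitted
     membrane half-thickness in Angstrom (full hydrophobic thickness is
     twice this value).  Entries without the element are skipped. -->
<pdbtm>
  <entry id="1abc">
    <membrane>
      <half_thickness>15.2</half_thickness>
    </membrane>
  </entry>
  <entry id="2def">
    <membrane>
      <half_thickness>12.75</half_thickness>
    </membrane>
  </entry>
  <entry id="3ghi">
    <membrane/>
  </entry>
</pdbtm>
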