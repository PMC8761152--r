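<?xml version="1.0" encoding="UTF-8"?>
<!-- Topology annotation dialect read by parse_topology_xml():
     one <protein> per entry with id, sequence length and prediction
     reliability; <region> children tile [1, length] with labels
     I = inside loop, O = outside loop, M = membrane-spanning segment,
     L = re-entrant membrane loop (excluded from side assignment). -->
<topologies>
  <protein id="P_SINGLE" length="40" reliability="99.1">
    <region start="1" end="10" label="I"/>
    <region start="11" end="30" label="M"/>
    <region start="31" end="40" label="O"/>
  </protein>
  <protein id="P_DOUBLE" length="60" reliability="95.3">
    <region start="1" end="5" label="I"/>
    <region start="6" end="25" label="M"/>
    <region start="26" end="32" label="O"/>
    <region start="33" end="52" label="M"/>
    <region start="53" end="60" label="I"/>
  </protein>
  <protein id="P_SOLUBLE" length="25" reliability="80.0">
    <region start="1" end="25" label="I"/>
  </protein>
</topologies>
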