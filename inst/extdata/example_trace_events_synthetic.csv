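"user","neuron","timestamp","action"
"tracer1",1,0,"node_added"
"tracer1",1,45,"node_added"
"tracer1",1,130,"node_added"
"tracer1",1,400,"node_added"
"tracer1",1,460,"node_added"
"tracer1",1,505,"node_added"
"tracer2",1,20,"node_added"
"tracer2",1,90,"node_added"
"tracer2",1,150,"node_added"
"tracer2",1,600,"node_added"
"tracer2",1,640,"node_added"
"tracer2",1,700,"node_added"
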